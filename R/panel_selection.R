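#' Enumerate odd-sized rater subsets for majority voting
#'
#' All `choose(n, k)` subsets of the rater pool, in lexicographic order of
#' the sorted rater ids, e.g. 3-of-4 over A-D gives ABC, ABD, ACD, BCD.
#' `k` must be odd so a strict majority always exists.
#'
#' @param rater_ids character vector of unique rater identifiers.
#' @param k subset size; odd, between 1 and `length(rater_ids)`.
#' @return list of character vectors, each a sorted rater subset.
#' @examples
#' enumerate_majority_combinations(c("A", "B", "C", "D"), 3)
#' @export
enumerate_majority_combinations <- function(rater_ids, k) {
  rater_ids <- as.character(rater_ids)
  if (anyDuplicated(rater_ids)) stop("rater ids must be unique", call. = FALSE)
  if (k %% 2L == 0L || k < 1L || k > length(rater_ids)) {
    stop("`k` must be odd and within 1..number of raters", call. = FALSE)
  }
  ids <- sort(rater_ids)
  combs <- utils::combn(ids, k, simplify = FALSE)
  combs
}

#' Select the F1-best rater subset by majority vote
#'
#' For every odd subset of size `k`, forms the per-case majority vote,
#' scores it against truth, and returns the subset with the highest F1
#' alongside the full per-subset metric table. F1 ties break
#' lexicographically on the sorted rater ids, so the result is
#' deterministic and invariant to the order raters are supplied in.
#'
#' @param truth vector of true depth labels.
#' @param votes_by_rater data.frame or matrix of votes, one column per
#'   rater (named), one row per case, aligned to `truth`; no missing votes.
#' @param k subset size (odd).
#' @return list with `subset` (character vector of winning rater ids),
#'   `metrics` (data.frame, one row per subset with a `raters` column and
#'   the six statistics) and `per_subset` (named list of `diag_metrics`).
#' @examples
#' votes <- data.frame(A = c("SM", "M"), B = c("SM", "M"), C = c("M", "SM"))
#' select_best_panel(c("SM", "M"), votes, k = 3)$subset
#' @export
select_best_panel <- function(truth, votes_by_rater, k) {
  truth <- as_depth_label(truth, "truth")
  votes <- as.data.frame(votes_by_rater, stringsAsFactors = FALSE)
  if (nrow(votes) != length(truth)) {
    stop("votes and truth must describe the same cases", call. = FALSE)
  }
  if (anyNA(votes)) stop("missing votes are not allowed", call. = FALSE)
  combs <- enumerate_majority_combinations(names(votes), k)
  per_subset <- lapply(combs, function(ids) {
    calls <- aggregate_panel(votes[, ids, drop = FALSE])
    metrics_from_confusion(confusion_from_labels(truth, calls$label))
  })
  names(per_subset) <- vapply(combs, paste, character(1), collapse = "")
  tab <- do.call(rbind, lapply(per_subset, as.data.frame))
  tab <- cbind(raters = names(per_subset), tab)
  rownames(tab) <- NULL
  f1 <- vapply(per_subset, `[[`, numeric(1), "f1")
  # combs are already lexicographic, which.max keeps the first of any tie
  list(subset = combs[[which.max(f1)]], metrics = tab,
       per_subset = per_subset)
}
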
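#' Confidence-stratified call from a classifier probability
#'
#' Converts the classifier's probability that a lesion is submucosal
#' (`p_sm`, a softmax-style value in `[0, 1]`) into a depth call with a
#' confidence level. The label is SM when `p_sm > 0.5`, M otherwise. The
#' diagnostic probability is the probability of the chosen class,
#' `q = max(p_sm, 1 - p_sm)`; `q > 0.75` is high confidence, anything else
#' (the `(0.5, 0.75]` band) low confidence.
#'
#' At `p_sm = 0.5` exactly, the default call is M with low confidence, so a
#' coin-flip score never inflates the positive (SM) class;
#' `ties = "SM"` flips that convention.
#'
#' @param p_sm numeric vector of probabilities in `[0, 1]`.
#' @param ties label assigned at `p_sm == 0.5`, `"M"` (default) or `"SM"`.
#' @return a data.frame with one row per probability: `label` (factor
#'   M/SM), `confidence` (ordered factor low < high).
#' @examples
#' stratify_ai(c(0.9, 0.75, 0.6, 0.1))
#' @export
stratify_ai <- function(p_sm, ties = c("M", "SM")) {
  ties <- match.arg(ties)
  if (!is.numeric(p_sm) || anyNA(p_sm) || any(p_sm < 0 | p_sm > 1)) {
    stop("`p_sm` must be probabilities in [0, 1]", call. = FALSE)
  }
  label <- ifelse(p_sm > 0.5, "SM", ifelse(p_sm < 0.5, "M", ties))
  q <- pmax(p_sm, 1 - p_sm)
  data.frame(
    label = as_depth_label(label),
    confidence = as_confidence(ifelse(q > 0.75, "high", "low"))
  )
}

#' Majority vote and unanimity confidence of a rater panel
#'
#' An odd-sized panel's call is the strict majority of its votes; the call
#' carries high confidence if and only if the vote is unanimous, low
#' confidence otherwise. A panel of one is permitted and is trivially
#' unanimous.
#'
#' @param votes depth labels (`"M"`/`"SM"`), one per rater; odd length. A
#'   matrix or data.frame of labels (cases x raters, odd column count) is
#'   aggregated row-wise.
#' @return for a vector, a one-row data.frame with `label` and
#'   `confidence`; for a matrix/data.frame, one row per case.
#' @examples
#' aggregate_panel(c("SM", "SM", "M"))
#' @export
aggregate_panel <- function(votes) {
  if (is.matrix(votes) || is.data.frame(votes)) {
    vm <- as.matrix(votes)
    if (ncol(vm) %% 2L == 0L || ncol(vm) < 1L) {
      stop("panel size must be odd and >= 1", call. = FALSE)
    }
    res <- apply(vm, 1L, function(v) {
      one <- aggregate_panel(v)
      c(as.character(one$label), as.character(one$confidence))
    })
    return(data.frame(label = as_depth_label(res[1, ]),
                      confidence = as_confidence(res[2, ])))
  }
  votes <- as_depth_label(votes, "votes")
  k <- length(votes)
  if (k %% 2L == 0L || k < 1L) {
    stop("panel size must be odd and >= 1", call. = FALSE)
  }
  n_sm <- sum(votes == "SM")
  data.frame(
    label = as_depth_label(if (n_sm * 2L > k) "SM" else "M"),
    confidence = as_confidence(if (n_sm == 0L || n_sm == k) "high" else "low")
  )
}
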
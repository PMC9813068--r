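#' Fusion patterns
#'
#' The four fixed rules for resolving a same-confidence disagreement
#' between the classifier and the panel. Mismatch 1 is "AI says SM, panel
#' says M"; mismatch 2 is "AI says M, panel says SM".
#' \describe{
#'   \item{I}{AI wins both mismatches.}
#'   \item{II}{panel wins mismatch 1, AI wins mismatch 2.}
#'   \item{III}{AI wins mismatch 1, panel wins mismatch 2.}
#'   \item{IV}{panel wins both mismatches.}
#' }
#' @return character vector `c("I", "II", "III", "IV")`.
#' @export
fusion_patterns <- function() c("I", "II", "III", "IV")

# who wins each mismatch under each pattern
.pattern_rules <- list(
  I   = c(mismatch1 = "ai",    mismatch2 = "ai"),
  II  = c(mismatch1 = "panel", mismatch2 = "ai"),
  III = c(mismatch1 = "ai",    mismatch2 = "panel"),
  IV  = c(mismatch1 = "panel", mismatch2 = "panel")
)

#' Fuse one or more paired confidence-stratified calls
#'
#' Applies the cooperative decision table cell by cell:
#' \enumerate{
#'   \item labels agree: that label is final (route `"agreement"`; the
#'     pattern is irrelevant);
#'   \item labels differ, confidences differ: the higher-confidence source
#'     wins (route `"confidence_override"`);
#'   \item labels differ at equal confidence: the case is mismatch 1 (AI
#'     SM, panel M) or mismatch 2 (AI M, panel SM), resolved by `pattern`.
#' }
#'
#' @param ai data.frame with `label` and `confidence` columns as returned
#'   by [stratify_ai()] (one row per case).
#' @param panel data.frame with `label` and `confidence` as returned by
#'   [aggregate_panel()], aligned to `ai`.
#' @param pattern one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return data.frame with `final_label` (factor M/SM) and `route` (factor:
#'   agreement, confidence_override, mismatch1, mismatch2), one row per
#'   case, input order preserved.
#' @examples
#' ai <- stratify_ai(c(0.9, 0.8, 0.4))
#' panel <- aggregate_panel(rbind(c("M", "M", "M"), c("M", "M", "M"),
#'                                c("SM", "SM", "M")))
#' fuse_case(ai, panel, pattern = "III")
#' @export
fuse_case <- function(ai, panel, pattern = fusion_patterns()) {
  pattern <- match.arg(pattern)
  ai_label <- as_depth_label(ai$label, "ai$label")
  panel_label <- as_depth_label(panel$label, "panel$label")
  ai_conf <- as_confidence(ai$confidence, "ai$confidence")
  panel_conf <- as_confidence(panel$confidence, "panel$confidence")
  n <- length(ai_label)
  if (length(panel_label) != n) {
    stop("`ai` and `panel` must describe the same cases", call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(final_label = as_depth_label(character()),
                      route = factor(character(), levels = .routes())))
  }
  final <- character(n)
  route <- character(n)
  agree <- ai_label == panel_label
  final[agree] <- as.character(ai_label[agree])
  route[agree] <- "agreement"

  override <- !agree & ai_conf != panel_conf
  final[override] <- ifelse(ai_conf[override] > panel_conf[override],
                            as.character(ai_label[override]),
                            as.character(panel_label[override]))
  route[override] <- "confidence_override"

  mism <- !agree & ai_conf == panel_conf
  m1 <- mism & ai_label == "SM"   # panel necessarily M
  m2 <- mism & ai_label == "M"    # panel necessarily SM
  route[m1] <- "mismatch1"
  route[m2] <- "mismatch2"
  rule <- .pattern_rules[[pattern]]
  final[m1] <- if (rule[["mismatch1"]] == "ai") "SM" else "M"
  final[m2] <- if (rule[["mismatch2"]] == "ai") "M" else "SM"

  data.frame(final_label = as_depth_label(final),
             route = factor(route, levels = .routes()))
}

.routes <- function() c("agreement", "confidence_override",
                        "mismatch1", "mismatch2")

#' Fuse a cohort of paired calls
#'
#' Elementwise [fuse_case()] over a cohort; kept as a separate verb so
#' pipelines read naturally.
#'
#' @inheritParams fuse_case
#' @return see [fuse_case()].
#' @export
fuse_cohort <- function(ai, panel, pattern = fusion_patterns()) {
  fuse_case(ai, panel, pattern)
}

#' Select the F1-best mismatch-resolution pattern on training data
#'
#' Evaluates all four patterns on a training cohort via [fuse_cohort()] and
#' [metrics_from_confusion()], and returns the pattern with the highest F1
#' together with the full four-pattern metric table. Ties break toward the
#' lowest-numbered pattern so the result is deterministic.
#'
#' @param truth vector of true depth labels.
#' @param ai,panel confidence-stratified calls aligned to `truth` (see
#'   [fuse_case()]).
#' @return list with components `pattern` (the selected pattern), `metrics`
#'   (data.frame, one row per pattern: accuracy, sensitivity, specificity,
#'   ppv, npv, f1), and `per_pattern` (named list of `diag_metrics`).
#' @examples
#' ai <- stratify_ai(c(0.9, 0.85, 0.3, 0.2))
#' panel <- aggregate_panel(rbind(c("M","M","M"), c("SM","SM","SM"),
#'                                c("M","M","M"), c("SM","SM","M")))
#' select_pattern(c("SM", "SM", "M", "M"), ai, panel)$pattern
#' @export
select_pattern <- function(truth, ai, panel) {
  truth <- as_depth_label(truth, "truth")
  if (length(truth) == 0L) stop("empty cohort", call. = FALSE)
  if (length(unique(truth)) < 2L) {
    stop("both classes must be present to compare patterns by F1",
         call. = FALSE)
  }
  per_pattern <- lapply(fusion_patterns(), function(p) {
    out <- fuse_cohort(ai, panel, pattern = p)
    metrics_from_confusion(confusion_from_labels(truth, out$final_label))
  })
  names(per_pattern) <- fusion_patterns()
  tab <- do.call(rbind, lapply(per_pattern, as.data.frame))
  tab <- cbind(pattern = fusion_patterns(), tab)
  rownames(tab) <- NULL
  f1 <- vapply(per_pattern, `[[`, numeric(1), "f1")
  best <- fusion_patterns()[which.max(f1)]  # which.max takes first on ties
  list(pattern = best, metrics = tab, per_pattern = per_pattern)
}
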
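#' Read and write case-level cohort CSV files
#'
#' The interchange format is a UTF-8 comma-separated file with a header
#' and the fixed column set `case_id, truth, sm_stage, p_sm,
#' vote_<raterid>..., diameter_mm, histology`. Labels are the literal
#' strings `"M"`/`"SM"`, probabilities decimals in `[0, 1]`. Reading
#' validates every cell and reports the offending row and column;
#' `write_cohort()` then `read_cohort()` is the identity on values.
#'
#' @param path file path.
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @return `read_cohort()`: the validated cohort data.frame;
#'   `write_cohort()`: the path, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  fixed <- c("case_id", "truth", "sm_stage", "p_sm", "diameter_mm",
             "histology")
  vote_cols <- grep("^vote_", names(d), value = TRUE)
  unknown <- setdiff(names(d), c(fixed, vote_cols))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(fixed, names(d))
  if (length(missing) > 0L) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (length(vote_cols) == 0L) {
    stop("cohort file has no vote_* columns", call. = FALSE)
  }
  cell_error <- function(row, col, why) {
    stop(sprintf("invalid value at row %d, column %s: %s", row, col, why),
         call. = FALSE)
  }
  if (anyDuplicated(d$case_id)) {
    dup <- which(duplicated(d$case_id))[1]
    cell_error(dup, "case_id", sprintf("duplicate id \"%s\"", d$case_id[dup]))
  }
  check_labels <- function(col, allow_na = FALSE) {
    v <- d[[col]]
    bad <- !(v %in% c("M", "SM") | (allow_na & (is.na(v) | v == "")))
    if (any(bad)) cell_error(which(bad)[1], col,
                             sprintf("\"%s\" is not M or SM", v[which(bad)[1]]))
  }
  check_labels("truth")
  for (vc in vote_cols) check_labels(vc)
  bad_stage <- !(d$sm_stage %in% c("SM1", "SM2") |
                   is.na(d$sm_stage) | d$sm_stage == "")
  if (any(bad_stage)) cell_error(which(bad_stage)[1], "sm_stage",
                                 "must be SM1, SM2 or empty")
  num <- function(col, lo = -Inf, hi = Inf) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- is.na(v) | v < lo | v > hi
    if (any(bad)) cell_error(which(bad)[1], col,
                             sprintf("\"%s\" is not a number in [%s, %s]",
                                     d[[col]][which(bad)[1]], lo, hi))
    v
  }
  d$p_sm <- num("p_sm", 0, 1)
  d$diameter_mm <- num("diameter_mm", lo = 0)
  bad_hist <- !d$histology %in% c("differentiated", "undifferentiated")
  if (any(bad_hist)) cell_error(which(bad_hist)[1], "histology",
                                "must be differentiated or undifferentiated")
  d$sm_stage[d$sm_stage == ""] <- NA_character_
  d$truth <- as_depth_label(d$truth)
  d
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$truth <- as.character(out$truth)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full cooperative-diagnosis pipeline
#'
#' Chains the stages of the study on a training cohort and (optionally) an
#' independent test cohort:
#' \enumerate{
#'   \item per-rater diagnostic metrics on training;
#'   \item majority-vote panel selection: the F1-best subset of `k` raters
#'     ([select_best_panel()]);
#'   \item confidence stratification of the AI probability and the panel
#'     vote, with high/low-confidence accuracy comparison for both
#'     ([confidence_strata()]);
#'   \item fusion-pattern selection on training ([select_pattern()]);
#'   \item if a test cohort is given: AI-alone, panel-alone and
#'     cooperative metrics on test, using the training-selected panel and
#'     pattern.
#' }
#'
#' @param train training cohort data.frame (columns as in
#'   [read_cohort()]).
#' @param test optional test cohort with the same rater columns.
#' @param k panel size (odd); validated before any computation.
#' @return a `fusion_report` list: `per_rater` (metrics data.frame),
#'   `panel` (subset + per-subset table), `pattern` (selection result),
#'   `strata_ai`, `strata_panel`, `train_metrics` (AI / panel /
#'   cooperation on training) and, when `test` is supplied,
#'   `test_metrics` and `test_strata_*`; plus the echoed `config`s.
#' @examples
#' train <- generate_cohort(paper_preset("training_like", seed = 11))
#' rep <- run_pipeline(train, k = 3)
#' rep$pattern$pattern
#' @export
run_pipeline <- function(train, test = NULL, k = 3) {
  if (k %% 2L == 0L || k < 1L) {
    stop("panel size `k` must be odd and >= 1", call. = FALSE)
  }
  truth <- as_depth_label(train$truth, "train$truth")
  votes <- cohort_votes(train)

  # stage 1: individual raters
  per_rater <- do.call(rbind, lapply(names(votes), function(id) {
    m <- metrics_from_confusion(confusion_from_labels(truth, votes[[id]]))
    cbind(rater = id, as.data.frame(m))
  }))

  # stage 2: panel selection
  panel_sel <- select_best_panel(truth, votes, k = k)
  panel_calls <- aggregate_panel(votes[, panel_sel$subset, drop = FALSE])

  # stage 3: confidence stratification
  ai_calls <- stratify_ai(train$p_sm)
  strata_ai <- confidence_strata(truth, ai_calls)
  strata_panel <- confidence_strata(truth, panel_calls)

  # stage 4: fusion pattern selection
  pattern_sel <- select_pattern(truth, ai_calls, panel_calls)

  fused_train <- fuse_cohort(ai_calls, panel_calls, pattern_sel$pattern)
  train_metrics <- list(
    ai = metrics_from_confusion(confusion_from_labels(truth, ai_calls$label)),
    panel = metrics_from_confusion(
      confusion_from_labels(truth, panel_calls$label)),
    cooperation = metrics_from_confusion(
      confusion_from_labels(truth, fused_train$final_label))
  )

  report <- list(
    k = k,
    per_rater = per_rater,
    panel = panel_sel,
    strata_ai = strata_ai,
    strata_panel = strata_panel,
    pattern = pattern_sel,
    train_metrics = train_metrics,
    train_config = attr(train, "config")
  )

  # stage 5: independent test evaluation with frozen panel + pattern
  if (!is.null(test)) {
    t_truth <- as_depth_label(test$truth, "test$truth")
    t_votes <- cohort_votes(test)
    sub <- panel_sel$subset
    if (!all(sub %in% names(t_votes))) {
      # test cohort may carry its own (fewer) raters; fall back to all
      sub <- names(t_votes)[seq_len(min(k, length(names(t_votes))))]
    }
    t_panel <- aggregate_panel(t_votes[, sub, drop = FALSE])
    t_ai <- stratify_ai(test$p_sm)
    fused <- fuse_cohort(t_ai, t_panel, pattern_sel$pattern)
    report$test_metrics <- list(
      ai = metrics_from_confusion(confusion_from_labels(t_truth, t_ai$label)),
      panel = metrics_from_confusion(
        confusion_from_labels(t_truth, t_panel$label)),
      cooperation = metrics_from_confusion(
        confusion_from_labels(t_truth, fused$final_label))
    )
    report$test_strata_ai <- confidence_strata(t_truth, t_ai)
    report$test_strata_panel <- confidence_strata(t_truth, t_panel)
    report$test_config <- attr(test, "config")
  }
  structure(report, class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat(sprintf("cooperative-diagnosis report (panel k = %d)\n", x$k))
  cat(sprintf("selected panel: %s\n", paste(x$panel$subset, collapse = "")))
  cat(sprintf("selected pattern: %s\n", x$pattern$pattern))
  cat("training F1 - AI:", round(x$train_metrics$ai$f1, 3),
      " panel:", round(x$train_metrics$panel$f1, 3),
      " cooperation:", round(x$train_metrics$cooperation$f1, 3), "\n")
  if (!is.null(x$test_metrics)) {
    cat("test F1     - AI:", round(x$test_metrics$ai$f1, 3),
        " panel:", round(x$test_metrics$panel$f1, 3),
        " cooperation:", round(x$test_metrics$cooperation$f1, 3), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the metric tables as CSV and the whole report (including the
#' echoed generator configs with their seeds) as JSON under `dir`, so a
#' run is fully reproducible from its own artefacts.
#'
#' @param report a `fusion_report` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_rater, file.path(dir, "per_rater.csv"),
                   row.names = FALSE)
  utils::write.csv(report$panel$metrics, file.path(dir, "per_subset.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pattern$metrics, file.path(dir, "per_pattern.csv"),
                   row.names = FALSE)
  flat_metrics <- function(ml) lapply(ml, function(m) as.data.frame(m))
  json <- list(
    k = report$k,
    selected_panel = report$panel$subset,
    selected_pattern = report$pattern$pattern,
    train_metrics = flat_metrics(report$train_metrics),
    strata_ai = list(table = report$strata_ai$table,
                     accuracy_high = report$strata_ai$accuracy_high,
                     accuracy_low = report$strata_ai$accuracy_low,
                     chi_square = report$strata_ai$test$chi_square_statistic,
                     p_value = report$strata_ai$test$p_value),
    strata_panel = list(table = report$strata_panel$table,
                        accuracy_high = report$strata_panel$accuracy_high,
                        accuracy_low = report$strata_panel$accuracy_low,
                        chi_square = report$strata_panel$test$chi_square_statistic,
                        p_value = report$strata_panel$test$p_value),
    train_config = unclass(report$train_config)
  )
  if (!is.null(report$test_metrics)) {
    json$test_metrics <- flat_metrics(report$test_metrics)
    json$test_config <- unclass(report$test_config)
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
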
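#' Pluggable classifier protocol
#'
#' Evaluation harnesses ([leave_one_out()], [evaluate_holdout()]) are
#' generic over any classifier expressed as a fit/predict pair:
#' `fit(data, seed)` receives a training data.frame (with a `truth`
#' column) and returns an opaque fitted state; `predict_proba(state,
#' newdata)` returns the probability of SM for each new case. Both must be
#' deterministic given the seed.
#'
#' @param fit function(data, seed) -> fitted state.
#' @param predict_proba function(state, newdata) -> numeric vector of
#'   probabilities in `[0, 1]`.
#' @param name short label used in printing.
#' @return an object of class `df_classifier`.
#' @seealso [classifier_prescored()], [classifier_logistic()],
#'   [classifier_nearest_centroid()], [classifier_memorizer()],
#'   [classifier_constant()], [classifier_prevalence()]
#' @export
new_classifier <- function(fit, predict_proba, name = "classifier") {
  stopifnot(is.function(fit), is.function(predict_proba))
  structure(list(fit = fit, predict_proba = predict_proba, name = name),
            class = "df_classifier")
}

#' @export
print.df_classifier <- function(x, ...) {
  cat(sprintf("<classifier: %s>\n", x$name)); invisible(x)
}

#' Reference classifiers
#'
#' Simple classifiers shipped for testing and for running the pipeline on
#' synthetic cohorts; none involves deep learning.
#'
#' \describe{
#'   \item{`classifier_prescored()`}{returns a stored probability column
#'     (default `p_sm`) untouched; the natural choice when scores were
#'     produced upstream, as with the synthetic generator's calibrated
#'     probabilities. Fitting is a no-op.}
#'   \item{`classifier_logistic(features)`}{binomial GLM of truth on the
#'     named feature columns.}
#'   \item{`classifier_nearest_centroid(features)`}{class centroids in
#'     feature space; the SM probability is the unit-variance Gaussian
#'     posterior implied by the two centroid distances.}
#'   \item{`classifier_memorizer()`}{memorises the training cases' truth by
#'     `case_id` and predicts it with certainty, falling back to 0.5 for
#'     unseen ids. Its only purpose is as a leakage canary: under a correct
#'     leave-one-out protocol every prediction must be exactly 0.5.}
#'   \item{`classifier_constant(p)`}{always predicts `p`.}
#'   \item{`classifier_prevalence()`}{always predicts the training-fold SM
#'     prevalence.}
#' }
#'
#' @param column name of the probability column (prescored).
#' @param features character vector of feature column names.
#' @param id_column name of the case-identifier column (memorizer).
#' @param p constant probability.
#' @return a `df_classifier`.
#' @name reference_classifiers
NULL

#' @rdname reference_classifiers
#' @export
classifier_prescored <- function(column = "p_sm") {
  new_classifier(
    fit = function(data, seed) column,
    predict_proba = function(state, newdata) newdata[[state]],
    name = sprintf("prescored(%s)", column)
  )
}

#' @rdname reference_classifiers
#' @export
classifier_logistic <- function(features) {
  new_classifier(
    fit = function(data, seed) {
      f <- stats::as.formula(paste("I(truth == \"SM\") ~",
                                   paste(features, collapse = " + ")))
      suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
    },
    predict_proba = function(state, newdata) {
      as.numeric(stats::predict(state, newdata = newdata, type = "response"))
    },
    name = "logistic"
  )
}

#' @rdname reference_classifiers
#' @export
classifier_nearest_centroid <- function(features) {
  new_classifier(
    fit = function(data, seed) {
      x <- as.matrix(data[, features, drop = FALSE])
      list(
        mu_sm = colMeans(x[data$truth == "SM", , drop = FALSE]),
        mu_m  = colMeans(x[data$truth == "M", , drop = FALSE]),
        features = features
      )
    },
    predict_proba = function(state, newdata) {
      x <- as.matrix(newdata[, state$features, drop = FALSE])
      d_sm <- rowSums(sweep(x, 2, state$mu_sm)^2)
      d_m <- rowSums(sweep(x, 2, state$mu_m)^2)
      stats::plogis((d_m - d_sm) / 2)
    },
    name = "nearest-centroid"
  )
}

#' @rdname reference_classifiers
#' @export
classifier_memorizer <- function(id_column = "case_id") {
  new_classifier(
    fit = function(data, seed) {
      stats::setNames(as.character(data$truth), data[[id_column]])
    },
    predict_proba = function(state, newdata) {
      ids <- as.character(newdata[[id_column]])
      known <- ids %in% names(state)
      p <- rep(0.5, length(ids))
      p[known] <- ifelse(state[ids[known]] == "SM", 1, 0)
      p
    },
    name = "memorizer"
  )
}

#' @rdname reference_classifiers
#' @export
classifier_constant <- function(p) {
  force(p)
  new_classifier(
    fit = function(data, seed) p,
    predict_proba = function(state, newdata) rep(state, nrow(newdata)),
    name = sprintf("constant(%g)", p)
  )
}

#' @rdname reference_classifiers
#' @export
classifier_prevalence <- function() {
  new_classifier(
    fit = function(data, seed) mean(data$truth == "SM"),
    predict_proba = function(state, newdata) rep(state, nrow(newdata)),
    name = "prevalence"
  )
}

#' Leave-one-out evaluation of a classifier
#'
#' Runs the n-fold hold-one-out protocol: each case in turn is removed from
#' the cohort, the classifier is fitted on the remaining n - 1 cases, and
#' the held-out case is scored. Per-case predictions are assembled in input
#' order, stratified into high/low confidence ([stratify_ai()]), scored
#' against truth, and the two confidence strata compared by chi-square.
#' Folds run sequentially with per-fold seeds derived deterministically
#' from `seed`, so reports are bit-reproducible.
#'
#' @param data data.frame of cases with a `truth` column (`"M"`/`"SM"`)
#'   plus whatever columns the classifier consumes.
#' @param classifier a [new_classifier()] object.
#' @param seed master integer seed.
#' @return an `evaluation_report`: list with `p_sm` (per-case predicted SM
#'   probabilities), `calls` (label + confidence per case), `metrics`
#'   ([metrics_from_confusion()] on the pooled predictions), `strata` (see
#'   [confidence_strata()]), `n`, `n_folds`.
#' @examples
#' d <- data.frame(case_id = paste0("c", 1:6),
#'                 truth = rep(c("M", "SM"), 3), x = c(0, 1, 0.2, 0.9, 0.1, 1.1))
#' leave_one_out(d, classifier_nearest_centroid("x"), seed = 1)$metrics
#' @export
leave_one_out <- function(data, classifier, seed = 1L) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 2L) stop("leave-one-out needs at least 2 cases", call. = FALSE)
  truth <- as_depth_label(data$truth, "data$truth")
  p <- numeric(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (length(unique(train$truth)) < 2L) {
      stop(sprintf("fold %d: training part contains a single class", i),
           call. = FALSE)
    }
    fold_seed <- as.integer((seed + i) %% .Machine$integer.max)
    set.seed(fold_seed)
    state <- classifier$fit(train, fold_seed)
    pi_ <- classifier$predict_proba(state, data[i, , drop = FALSE])
    if (length(pi_) != 1L || is.na(pi_) || pi_ < 0 || pi_ > 1) {
      stop(sprintf("fold %d: classifier returned an invalid probability", i),
           call. = FALSE)
    }
    p[i] <- pi_
  }
  .evaluation_report(truth, p, n_folds = n)
}

#' Train/test evaluation of a classifier
#'
#' Fits once on the training cohort and scores every test case, producing
#' the same report as [leave_one_out()]. Train and test must not share case
#' ids (when both carry a `case_id` column).
#'
#' @param train,test data.frames of cases with a `truth` column.
#' @inheritParams leave_one_out
#' @return an `evaluation_report` on the test cases.
#' @export
evaluate_holdout <- function(train, test, classifier, seed = 1L) {
  train <- as.data.frame(train); test <- as.data.frame(test)
  if (!is.null(train$case_id) && !is.null(test$case_id) &&
      length(intersect(train$case_id, test$case_id)) > 0L) {
    stop("train and test share case ids", call. = FALSE)
  }
  truth <- as_depth_label(test$truth, "test$truth")
  seed <- as.integer(seed)
  set.seed(seed)
  state <- classifier$fit(train, seed)
  p <- classifier$predict_proba(state, test)
  if (length(p) != nrow(test) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("classifier returned invalid probabilities", call. = FALSE)
  }
  .evaluation_report(truth, p, n_folds = 1L)
}

.evaluation_report <- function(truth, p, n_folds) {
  calls <- stratify_ai(p)
  metrics <- metrics_from_confusion(confusion_from_labels(truth, calls$label))
  structure(list(
    p_sm = p,
    calls = calls,
    metrics = metrics,
    strata = confidence_strata(truth, calls),
    n = length(p),
    n_folds = n_folds
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation report: %d cases, %d fold(s)\n", x$n, x$n_folds))
  print(x$metrics)
  cat(sprintf("accuracy high confidence: %s, low confidence: %s\n",
              format(x$strata$accuracy_high, digits = 3),
              format(x$strata$accuracy_low, digits = 3)))
  invisible(x)
}

#' Compare accuracy between high- and low-confidence calls
#'
#' Cross-tabulates correct/incorrect against high/low confidence and tests
#' the association with the Pearson chi-square test ([chi_square_2x2()]).
#' If either stratum is empty the table is still returned but the test is
#' `NA` (a 2x2 test needs all four marginals).
#'
#' @param truth vector of true depth labels.
#' @param calls data.frame with `label` and `confidence` (as from
#'   [stratify_ai()] or [aggregate_panel()]).
#' @return list with `table` (2x2 counts, rows correct/incorrect, columns
#'   high/low), `accuracy_high`, `accuracy_low`, and `test` (a
#'   `strata_comparison` or `NULL` when undefined).
#' @export
confidence_strata <- function(truth, calls) {
  truth <- as_depth_label(truth, "truth")
  correct <- truth == as_depth_label(calls$label, "calls$label")
  conf <- as_confidence(calls$confidence, "calls$confidence")
  tab <- matrix(c(sum(correct & conf == "high"), sum(correct & conf == "low"),
                  sum(!correct & conf == "high"), sum(!correct & conf == "low")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("correct", "incorrect"), c("high", "low")))
  acc <- function(col) {
    s <- sum(tab[, col])
    if (s == 0) NA_real_ else tab["correct", col] / s
  }
  test <- if (all(rowSums(tab) >= 1) && all(colSums(tab) >= 1)) {
    chi_square_2x2(tab)
  } else NULL
  list(table = tab, accuracy_high = acc("high"), accuracy_low = acc("low"),
       test = test)
}
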
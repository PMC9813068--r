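#' Confusion counts from paired label vectors
#'
#' Tabulates a 2x2 confusion matrix with submucosal invasion (`"SM"`) as the
#' positive class: `tp` counts cases where truth and prediction are both SM,
#' `tn` where both are M.
#'
#' @param truth vector of true depth labels (`"M"`/`"SM"`).
#' @param predicted vector of predicted depth labels, same length.
#' @return an object of class `confusion_counts`: a list with integer
#'   components `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_from_labels(c("SM", "SM", "M", "M"), c("SM", "M", "M", "SM"))
#' @seealso [metrics_from_confusion()], [confusion_from_operating_point()]
#' @export
confusion_from_labels <- function(truth, predicted) {
  truth <- as_depth_label(truth, "truth")
  predicted <- as_depth_label(predicted, "predicted")
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(truth) < 1L) stop("need at least one case", call. = FALSE)
  new_confusion(
    tp = sum(truth == "SM" & predicted == "SM"),
    fp = sum(truth == "M" & predicted == "SM"),
    fn = sum(truth == "SM" & predicted == "M"),
    tn = sum(truth == "M" & predicted == "M")
  )
}

new_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion counts must sum to >= 1", call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("SM", "M"), predicted = c("SM", "M")))
  cat("2x2 confusion counts (positive class: SM)\n")
  print(m)
  invisible(x)
}

#' Diagnostic-accuracy statistics from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value, and the F1 measure, the harmonic mean of sensitivity
#' and PPV: `2 * sens * PPV / (sens + PPV)`.
#'
#' A ratio whose denominator is zero (e.g. PPV when no case is called SM) is
#' reported as `NA`, never silently coerced to 0 or 1. F1 is computed in the
#' algebraically equivalent count form `2*tp / (2*tp + fp + fn)`, which
#' extends the harmonic mean continuously: it is 0 whenever there are no
#' true positives but some error, and `NA` only when tp, fp and fn are all
#' zero (no positive case exists or is called).
#'
#' @param x a `confusion_counts` object (or a list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @return an object of class `diag_metrics`: a list with numeric components
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `f1`, plus the
#'   counts under `counts`.
#' @examples
#' m <- metrics_from_confusion(confusion_from_labels(
#'   c("SM", "SM", "M", "M"), c("SM", "M", "M", "M")))
#' m$sensitivity
#' @export
metrics_from_confusion <- function(x) {
  tp <- x$tp; fp <- x$fp; fn <- x$fn; tn <- x$tn
  n <- tp + fp + fn + tn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(
    accuracy    = ratio(tp + tn, n),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv         = ratio(tp, tp + fp),
    npv         = ratio(tn, tn + fn),
    f1          = f1,
    counts      = new_confusion(tp, fp, fn, tn)
  ), class = "diag_metrics")
}

#' @export
print.diag_metrics <- function(x, digits = 3, ...) {
  v <- unlist(x[c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")])
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.diag_metrics <- function(x, ...) {
  data.frame(accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, ppv = x$ppv, npv = x$npv,
             f1 = x$f1)
}

# round half away from zero; base round() rounds half to even, which would
# mis-reconstruct counts from percentages printed as *.5
round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct confusion counts from a printed operating point
#'
#' Given a (sensitivity, specificity) pair as printed in a results table and
#' the known class sizes, recovers the underlying 2x2 counts:
#' `tp = round(sens * n_pos)`, `tn = round(spec * n_neg)` (rounding half away
#' from zero), with `fn`/`fp` as complements. Feeding the result to
#' [metrics_from_confusion()] recovers the printed values to within half a
#' unit in the last digit, which makes whole published metric tables
#' recomputable from their own operating points.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @param n_pos,n_neg class sizes (number of true SM and true M cases).
#' @return a `confusion_counts` object.
#' @examples
#' confusion_from_operating_point(0.76, 0.78, 250, 250)
#' @export
confusion_from_operating_point <- function(sensitivity, specificity,
                                           n_pos, n_neg) {
  if (!is.numeric(sensitivity) || sensitivity < 0 || sensitivity > 1 ||
      !is.numeric(specificity) || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  if (n_pos < 1 || n_neg < 1) stop("class sizes must be >= 1", call. = FALSE)
  tp <- round_half_up(sensitivity * n_pos)
  tn <- round_half_up(specificity * n_neg)
  new_confusion(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' The statistic is computed from the closed form
#' `n * (ad - bc)^2 / ((a+b) (c+d) (a+c) (b+d))`, with the p-value from the
#' chi-square distribution on 1 degree of freedom. The Yates continuity
#' correction is off by default (`correct = FALSE`); setting
#' `correct = TRUE` subtracts `n/2` from `|ad - bc|` before squaring.
#' Typical use here is comparing correct/incorrect calls between the high-
#' and low-confidence strata of a diagnostic source.
#'
#' @param table a 2x2 matrix of non-negative counts with all four marginals
#'   at least 1.
#' @param correct logical; apply the Yates continuity correction.
#' @return an object of class `strata_comparison`: list with
#'   `chi_square_statistic`, `p_value`, `table`, `correct`.
#' @examples
#' chi_square_2x2(matrix(c(91, 73, 9, 27), 2, 2))
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) < 1) || any(colSums(table) < 1)) {
    stop("all four marginals must be >= 1", call. = FALSE)
  }
  storage.mode(table) <- "double"
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  # n*num^2 / ((a+b)(c+d)(a+c)(b+d)); as.numeric avoids integer overflow
  stat <- n * num^2 / (prod(as.numeric(rowSums(table))) *
                         prod(as.numeric(colSums(table))))
  structure(list(
    chi_square_statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    table = table,
    correct = correct
  ), class = "strata_comparison")
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat(sprintf("chi-square (1 df%s): %.4f, p = %.4g\n",
              if (x$correct) ", Yates-corrected" else "",
              x$chi_square_statistic, x$p_value))
  invisible(x)
}
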
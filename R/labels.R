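#' Depth labels
#'
#' Invasion-depth calls are binary: `"M"` (intramucosal, the negative class)
#' or `"SM"` (submucosal, the positive class throughout the package).
#' `as_depth_label()` validates and canonicalises a vector of labels into a
#' factor with levels `c("M", "SM")`.
#'
#' @param x character vector (or factor) of labels, each `"M"` or `"SM"`.
#' @param arg name used in error messages.
#' @return factor with levels `c("M", "SM")`.
#' @examples
#' as_depth_label(c("M", "SM", "SM"))
#' @export
as_depth_label <- function(x, arg = deparse(substitute(x))) {
  x <- as.character(x)
  bad <- !x %in% c("M", "SM")
  if (any(bad)) {
    stop(sprintf("invalid depth label in `%s`: %s (must be \"M\" or \"SM\")",
                 arg, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  factor(x, levels = c("M", "SM"))
}

#' @rdname as_depth_label
#' @export
depth_levels <- function() c("M", "SM")

# internal: confidence levels, ordered low < high
confidence_levels <- function() c("low", "high")

as_confidence <- function(x, arg = deparse(substitute(x))) {
  x <- as.character(x)
  bad <- !x %in% confidence_levels()
  if (any(bad)) {
    stop(sprintf("invalid confidence level in `%s`: %s", arg,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  factor(x, levels = confidence_levels(), ordered = TRUE)
}
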
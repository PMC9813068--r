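#' Calibrate a binormal score model to a target operating point
#'
#' The generator represents a diagnostic score as a unit-variance Gaussian
#' latent: `s ~ N(0, 1)` for intramucosal (M) cases and `s ~ N(delta, 1)`
#' for submucosal (SM) cases, dichotomised at a threshold `t`. Given a
#' target (sensitivity, specificity) this returns the unique `(delta, t)`
#' with `spec = pnorm(t)` and `sens = pnorm(delta - t)`, i.e.
#' `t = qnorm(spec)` and `delta = qnorm(spec) + qnorm(sens)`, so the
#' thresholded score attains the target operating point exactly in
#' expectation.
#'
#' @param sens,spec target sensitivity and specificity, strictly inside
#'   (0, 1) (the boundary has no finite threshold).
#' @return list with components `delta` (class separation) and `t`
#'   (decision threshold), class `binormal_calibration`.
#' @examples
#' calibrate_binormal(0.76, 0.78)
#' @export
calibrate_binormal <- function(sens, spec) {
  if (!is.numeric(sens) || !is.numeric(spec) ||
      sens <= 0 || sens >= 1 || spec <= 0 || spec >= 1) {
    stop("sens and spec must lie strictly inside (0, 1)", call. = FALSE)
  }
  t <- stats::qnorm(spec)
  structure(list(delta = t + stats::qnorm(sens), t = t),
            class = "binormal_calibration")
}

#' Cohort generator configuration
#'
#' Collects and validates everything [generate_cohort()] needs: class
#' sizes, the AI classifier's target operating point, per-rater operating
#' points, the inter-rater correlation, and nuisance covariate settings.
#'
#' Rater votes follow a one-factor latent model: each case draws a shared
#' standard-normal factor `c`; rater `r` sees `u_r = sqrt(rho) * c +
#' sqrt(1 - rho) * e_r` with independent standard-normal noise `e_r`, and
#' votes SM when `u_r` exceeds the class-specific quantile
#' `qnorm(1 - h)` where `h` is that rater's SM-vote rate for the case's
#' class (its sensitivity on SM cases, one minus its specificity on M
#' cases). Because `u_r` is marginally standard normal for every `rho`,
#' each rater's (sensitivity, specificity) matches its target in
#' expectation regardless of the correlation.
#'
#' `covariate_effect` (default 0) shifts the AI latent score of truth-M
#' lesions that are large (diameter > 30 mm) or undifferentiated toward
#' the SM side, mimicking the classifier's documented weakness on such
#' lesions; it leaves rater votes untouched.
#'
#' @param n_pos,n_neg number of SM and M cases.
#' @param ai_sens,ai_spec AI target operating point, in (0, 1).
#' @param rater_ops named list, one entry per rater, each a numeric vector
#'   `c(sens, spec)` in (0, 1).
#' @param rho inter-rater latent correlation in `[0, 1]`.
#' @param covariate_effect non-negative shift of the AI latent for large or
#'   undifferentiated truth-M lesions.
#' @param p_sm1 probability that an SM case is annotated SM1 rather than
#'   SM2 (annotation only; no effect on generation).
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_pos, n_neg, ai_sens, ai_spec, rater_ops,
                          rho = 0.5, covariate_effect = 0, p_sm1 = 0.38,
                          seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  chk_prop <- function(x, what) {
    if (!is.numeric(x) || any(x <= 0) || any(x >= 1)) {
      stop(sprintf("%s must lie strictly inside (0, 1)", what), call. = FALSE)
    }
  }
  chk_prop(ai_sens, "ai_sens"); chk_prop(ai_spec, "ai_spec")
  chk_prop(p_sm1, "p_sm1")
  if (!is.list(rater_ops) || is.null(names(rater_ops)) ||
      anyDuplicated(names(rater_ops))) {
    stop("rater_ops must be a named list with unique rater ids",
         call. = FALSE)
  }
  for (id in names(rater_ops)) {
    op <- rater_ops[[id]]
    if (length(op) != 2L) stop("each rater_ops entry must be c(sens, spec)",
                               call. = FALSE)
    chk_prop(op, sprintf("rater %s operating point", id))
  }
  if (!is.numeric(rho) || rho < 0 || rho > 1) {
    stop("rho must lie in [0, 1]", call. = FALSE)
  }
  if (covariate_effect < 0) stop("covariate_effect must be >= 0",
                                 call. = FALSE)
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    ai_sens = ai_sens, ai_spec = ai_spec, rater_ops = rater_ops,
    rho = rho, covariate_effect = covariate_effect, p_sm1 = p_sm1,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Preset configurations mirroring the study design
#'
#' `"training_like"` emulates the internal-evaluation cohort: 250 SM and
#' 250 M cases, AI at (0.76, 0.78), and four expert raters A-D at their
#' published per-rater operating points (A 0.616/0.760, B 0.544/0.892,
#' C 0.432/0.900, D 0.600/0.696); 38% of SM cases are annotated SM1.
#' `"test_like"` emulates the independent test cohort: 100/100 cases, AI
#' at (0.74, 0.71), and a three-rater panel whose members each carry the
#' panel-level operating point (0.52, 0.88) with a high inter-rater
#' correlation (the majority vote of identically calibrated raters
#' approaches that same operating point as the correlation approaches 1);
#' 26% of SM cases are SM1.
#'
#' @param name `"training_like"` or `"test_like"`.
#' @param rho inter-rater correlation override.
#' @param seed integer seed stored in the config.
#' @return a `cohort_config`.
#' @examples
#' paper_preset("training_like")$rater_ops$A
#' @export
paper_preset <- function(name = c("training_like", "test_like"),
                         rho = NULL, seed = 1L) {
  name <- match.arg(name)
  if (name == "training_like") {
    cohort_config(
      n_pos = 250, n_neg = 250, ai_sens = 0.76, ai_spec = 0.78,
      rater_ops = list(A = c(0.616, 0.760), B = c(0.544, 0.892),
                       C = c(0.432, 0.900), D = c(0.600, 0.696)),
      rho = if (is.null(rho)) 0.5 else rho,
      p_sm1 = 95 / 250, seed = seed
    )
  } else {
    cohort_config(
      n_pos = 100, n_neg = 100, ai_sens = 0.74, ai_spec = 0.71,
      rater_ops = list(A = c(0.52, 0.88), B = c(0.52, 0.88),
                       C = c(0.52, 0.88)),
      rho = if (is.null(rho)) 0.8 else rho,
      p_sm1 = 26 / 100, seed = seed
    )
  }
}

#' Generate a synthetic case-level cohort
#'
#' Produces a cohort with exactly the configured class sizes, an AI
#' probability column calibrated so that thresholding `p_sm` at 0.5
#' attains the target AI operating point in expectation, and one vote
#' column per rater from the correlated one-factor model described in
#' [cohort_config()].
#'
#' The AI probability is the equal-prior binormal posterior recentred at
#' the calibrated threshold: `p_sm = plogis(delta * (s - t))`, a strictly
#' monotone transform of the latent score `s` (when `delta > 0`) that puts
#' the `p_sm = 0.5` boundary exactly at `s = t`. Confidence strata derived
#' from `p_sm` ([stratify_ai()]) therefore order cases by distance from
#' the decision boundary.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `case_id`, `truth`, `sm_stage` (`SM1`/
#'   `SM2` for SM cases, `NA` for M), `p_sm`, one `vote_<id>` column per
#'   rater, `diameter_mm`, `histology`; the config is attached as
#'   attribute `"config"`. Deterministic given the config (seed included).
#' @examples
#' cohort <- generate_cohort(paper_preset("training_like", seed = 7))
#' table(cohort$truth)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config", call. = FALSE)
  }
  set.seed(config$seed)
  n_pos <- config$n_pos; n_neg <- config$n_neg
  n <- n_pos + n_neg
  truth <- as_depth_label(rep(c("M", "SM"), c(n_neg, n_pos)))

  # covariates first so the AI score can depend on them
  diameter <- round(stats::rlnorm(n, meanlog = log(22), sdlog = 0.45), 1)
  histology <- sample(c("differentiated", "undifferentiated"), n,
                      replace = TRUE, prob = c(0.65, 0.35))
  sm_stage <- rep(NA_character_, n)
  sm_stage[truth == "SM"] <-
    ifelse(stats::rbinom(n_pos, 1, config$p_sm1) == 1, "SM1", "SM2")

  # AI latent score: binormal, covariate shift for hard M lesions
  cal <- calibrate_binormal(config$ai_sens, config$ai_spec)
  s <- stats::rnorm(n, mean = ifelse(truth == "SM", cal$delta, 0), sd = 1)
  hard_m <- truth == "M" & (diameter > 30 | histology == "undifferentiated")
  s[hard_m] <- s[hard_m] + config$covariate_effect
  p_sm <- stats::plogis(cal$delta * (s - cal$t))

  # correlated rater votes: shared case factor + idiosyncratic noise
  rho <- config$rho
  shared <- stats::rnorm(n)
  votes <- lapply(names(config$rater_ops), function(id) {
    op <- config$rater_ops[[id]]
    u <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
    hit <- ifelse(truth == "SM", op[1], 1 - op[2])  # P(vote SM | class)
    ifelse(u > stats::qnorm(1 - hit), "SM", "M")
  })
  names(votes) <- paste0("vote_", names(config$rater_ops))

  out <- data.frame(
    case_id = sprintf("case_%05d", seq_len(n)),
    truth = truth,
    sm_stage = sm_stage,
    p_sm = p_sm,
    votes,
    diameter_mm = diameter,
    histology = histology,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  out
}

#' Rater vote columns of a cohort
#'
#' Convenience accessor: the `vote_<id>` columns of a cohort as a
#' data.frame named by rater id.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()] or
#'   [read_cohort()]).
#' @return data.frame of votes, one column per rater.
#' @export
cohort_votes <- function(cohort) {
  cols <- grep("^vote_", names(cohort), value = TRUE)
  if (length(cols) == 0L) stop("cohort has no vote_* columns", call. = FALSE)
  out <- cohort[, cols, drop = FALSE]
  names(out) <- sub("^vote_", "", cols)
  out
}
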
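test_that("binormal calibration inverts the target operating point", {
  cal <- calibrate_binormal(0.5, 0.5)
  expect_equal(cal$delta, 0)
  expect_equal(cal$t, 0)
  # half specificity pins the threshold at the null mean
  cal <- calibrate_binormal(0.9, 0.5)
  expect_equal(cal$t, 0)
  expect_equal(cal$delta, qnorm(0.9))

  # numeric-integration oracle: tail masses of the two latent normals
  cal <- calibrate_binormal(0.76, 0.78)
  sens <- integrate(function(x) dnorm(x, mean = cal$delta), cal$t, Inf)$value
  spec <- integrate(dnorm, -Inf, cal$t)$value
  expect_equal(sens, 0.76, tolerance = 1e-8)
  expect_equal(spec, 0.78, tolerance = 1e-8)

  expect_error(calibrate_binormal(1, 0.5), "strictly inside")
})

test_that("presets carry the published design", {
  cfg <- paper_preset("training_like")
  expect_equal(cfg$n_pos, 250L)
  expect_equal(cfg$n_neg, 250L)
  expect_equal(c(cfg$ai_sens, cfg$ai_spec), c(0.76, 0.78))
  expect_equal(cfg$rater_ops$A, c(0.616, 0.760))
  expect_equal(cfg$rater_ops$C, c(0.432, 0.900))
  expect_equal(cfg$p_sm1, 0.38)

  cfg <- paper_preset("test_like")
  expect_equal(cfg$n_pos, 100L)
  expect_equal(c(cfg$ai_sens, cfg$ai_spec), c(0.74, 0.71))
  expect_equal(cfg$rater_ops$B, c(0.52, 0.88))

  expect_error(paper_preset("validation_like"), "arg")
})

test_that("cohorts are valid, exactly balanced and deterministic", {
  cfg <- paper_preset("training_like", seed = 77)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 500L)
  expect_equal(sum(cohort$truth == "SM"), 250L)
  expect_true(all(cohort$p_sm >= 0 & cohort$p_sm <= 1))
  # SM stage annotated iff truth is SM
  expect_true(all(is.na(cohort$sm_stage[cohort$truth == "M"])))
  expect_true(all(cohort$sm_stage[cohort$truth == "SM"] %in% c("SM1", "SM2")))
  expect_equal(sort(names(cohort_votes(cohort))), c("A", "B", "C", "D"))
  expect_false(anyDuplicated(cohort$case_id) > 0)

  # byte-level determinism after serialisation
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(cohort, f1)
  write_cohort(generate_cohort(paper_preset("training_like", seed = 77)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different cohort
  other <- generate_cohort(paper_preset("training_like", seed = 78))
  expect_false(identical(cohort$p_sm, other$p_sm))
})

test_that("thresholding p_sm at 0.5 hits the target operating point", {
  cfg <- cohort_config(n_pos = 20000, n_neg = 20000, ai_sens = 0.76,
                       ai_spec = 0.78, rater_ops = list(A = c(0.6, 0.8)),
                       rho = 0.5, seed = 303)
  cohort <- generate_cohort(cfg)
  calls <- stratify_ai(cohort$p_sm)
  m <- metrics_from_confusion(confusion_from_labels(cohort$truth,
                                                    calls$label))
  se <- function(p) sqrt(p * (1 - p) / 20000)
  expect_lt(abs(m$sensitivity - 0.76), 3 * se(0.76))
  expect_lt(abs(m$specificity - 0.78), 3 * se(0.78))
  # rater marginal recovery at the same size
  votes <- cohort_votes(cohort)
  sens_A <- mean(votes$A[cohort$truth == "SM"] == "SM")
  spec_A <- mean(votes$A[cohort$truth == "M"] == "M")
  expect_lt(abs(sens_A - 0.6), 3 * se(0.6))
  expect_lt(abs(spec_A - 0.8), 3 * se(0.8))
})

test_that("perfectly correlated same-operating-point raters vote as one", {
  cfg <- cohort_config(n_pos = 300, n_neg = 300, ai_sens = 0.7,
                       ai_spec = 0.7,
                       rater_ops = list(A = c(0.6, 0.8), B = c(0.6, 0.8),
                                        C = c(0.6, 0.8)),
                       rho = 1, seed = 99)
  votes <- cohort_votes(generate_cohort(cfg))
  expect_equal(votes$A, votes$B)
  expect_equal(votes$B, votes$C)
})

test_that("independent raters agree at the product of their marginals", {
  ops <- list(A = c(0.6, 0.8), B = c(0.7, 0.75))
  cfg <- cohort_config(n_pos = 20000, n_neg = 20000, ai_sens = 0.7,
                       ai_spec = 0.7, rater_ops = ops, rho = 0, seed = 17)
  cohort <- generate_cohort(cfg)
  votes <- cohort_votes(cohort)
  for (cls in c("SM", "M")) {
    idx <- cohort$truth == cls
    pa <- if (cls == "SM") ops$A[1] else 1 - ops$A[2]  # P(A votes SM)
    pb <- if (cls == "SM") ops$B[1] else 1 - ops$B[2]
    expected <- pa * pb + (1 - pa) * (1 - pb)
    observed <- mean(votes$A[idx] == votes$B[idx])
    expect_lt(abs(observed - expected),
              3 * sqrt(expected * (1 - expected) / sum(idx)))
  }
})

test_that("a covariate effect raises the AI false-positive rate on hard M lesions", {
  cfg <- cohort_config(n_pos = 100, n_neg = 30000, ai_sens = 0.76,
                       ai_spec = 0.78, rater_ops = list(A = c(0.6, 0.8)),
                       covariate_effect = 1.0, seed = 55)
  cohort <- generate_cohort(cfg)
  m_cases <- cohort[cohort$truth == "M", ]
  hard <- m_cases$diameter_mm > 30 | m_cases$histology == "undifferentiated"
  fpr <- function(idx) mean(m_cases$p_sm[idx] > 0.5)
  expect_gt(fpr(hard), fpr(!hard))
})

test_that("config validation rejects out-of-range parameters", {
  ops <- list(A = c(0.6, 0.8))
  expect_error(cohort_config(10, 10, 1.0, 0.5, ops), "strictly inside")
  expect_error(cohort_config(10, 10, 0.7, 0.7, ops, rho = 1.2), "rho")
  expect_error(cohort_config(10, 10, 0.7, 0.7, list(c(0.6, 0.8))), "named")
  expect_error(cohort_config(10, 10, 0.7, 0.7,
                             list(A = c(0.6, 0.8), A = c(0.5, 0.5))),
               "named|unique")
  expect_error(generate_cohort(list(n_pos = 5)), "cohort_config")
})
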
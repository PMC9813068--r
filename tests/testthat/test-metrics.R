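test_that("confusion_from_labels tabulates the 2x2 with SM positive", {
  cc <- confusion_from_labels(c("SM", "SM", "M", "M"),
                              c("SM", "M", "M", "SM"))
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  # identity predictions leave no errors
  truth <- rep(c("M", "SM"), times = c(7, 5))
  cc <- confusion_from_labels(truth, truth)
  expect_equal(cc$fp + cc$fn, 0L)
  expect_equal(cc$tp, 5L)

  expect_error(confusion_from_labels(c("M", "SM"), "M"), "equal length")
  expect_error(confusion_from_labels(c("M", "X"), c("M", "M")),
               "invalid depth label")
})

test_that("components always sum to n and metrics stay in [0, 1]", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:80, 1)
    truth <- sample(c("M", "SM"), n, replace = TRUE)
    pred <- sample(c("M", "SM"), n, replace = TRUE)
    cc <- confusion_from_labels(truth, pred)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, n)
    m <- metrics_from_confusion(cc)
    v <- unlist(as.data.frame(m))
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
    # F1 between min and max of sensitivity and PPV when all defined
    if (!anyNA(c(m$sensitivity, m$ppv, m$f1)) &&
        m$sensitivity + m$ppv > 0) {
      expect_gte(m$f1, min(m$sensitivity, m$ppv) - 1e-12)
      expect_lte(m$f1, max(m$sensitivity, m$ppv) + 1e-12)
    }
  }
})

test_that("metrics match the published test-cohort columns", {
  # cooperation column of the independent test cohort
  m <- metrics_from_confusion(list(tp = 76, fp = 20, fn = 24, tn = 80))
  expect_equal(m$sensitivity, 0.760)
  expect_equal(m$specificity, 0.800)
  expect_equal(round(m$ppv, 4), 0.7917)
  expect_equal(round(m$f1, 4), 0.7755)

  # AI column of the same cohort
  m <- metrics_from_confusion(list(tp = 74, fp = 29, fn = 26, tn = 71))
  expect_equal(round(m$ppv, 4), 0.7184)
  expect_equal(round(m$npv, 4), 0.7320)
  expect_equal(round(m$f1, 4), 0.7291)

  # perfect classifier
  m <- metrics_from_confusion(list(tp = 3, fp = 0, fn = 0, tn = 9))
  expect_equal(unname(unlist(as.data.frame(m))), rep(1, 6))
})

test_that("undefined ratios surface as NA, F1 degenerates to 0 not 1", {
  # nothing called SM: PPV undefined, sensitivity 0, F1 0
  m <- metrics_from_confusion(list(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(is.na(m$ppv))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$f1, 0)
  # single-class all-negative truth, all-negative calls: F1 undefined
  m <- metrics_from_confusion(list(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$f1))
  expect_equal(m$accuracy, 1)
})

test_that("operating-point reconstruction recovers counts and round-trips", {
  expect_equal(unlist(confusion_from_operating_point(0.76, 0.78, 250, 250)),
               c(tp = 190L, fp = 55L, fn = 60L, tn = 195L))
  expect_equal(unlist(confusion_from_operating_point(0.536, 0.916, 250, 250)),
               c(tp = 134L, fp = 21L, fn = 116L, tn = 229L))
  expect_equal(unlist(confusion_from_operating_point(1, 1, 5, 5)),
               c(tp = 5L, fp = 0L, fn = 0L, tn = 5L))
  expect_error(confusion_from_operating_point(1.2, 0.5, 10, 10), "\\[0, 1\\]")

  # every published row: sens/spec round-trip to the printed decimal and
  # the balanced design forces accuracy = (sens + spec) / 2
  ops <- published_operating_points()
  for (i in seq_len(nrow(ops))) {
    cc <- confusion_from_operating_point(ops$sens[i], ops$spec[i],
                                         ops$n_pos[i], ops$n_neg[i])
    m <- metrics_from_confusion(cc)
    expect_equal(m$sensitivity, ops$sens[i], tolerance = 1e-12)
    expect_equal(m$specificity, ops$spec[i], tolerance = 1e-12)
    expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2,
                 tolerance = 1e-12)
  }
})

test_that("rounding is half away from zero, not banker's", {
  # 0.475 * 10 = 4.75 -> tp must round to 5 under half-up at .5 exactly:
  # use a case where base round() would go to even
  cc <- confusion_from_operating_point(0.45, 0.55, 10, 10)
  expect_equal(cc$tp, 5L)  # 4.5 rounds up (round() would give 4)
  expect_equal(cc$tn, 6L)  # 5.5 rounds up
})

test_that("Pearson chi-square matches closed form and stats::chisq.test", {
  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(flat$chi_square_statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2, 2))$chi_square_statistic,
               20)

  # cross-check against the independent base-R implementation
  set.seed(7)
  for (i in 1:10) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2, 2)
    ours <- chi_square_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$chi_square_statistic, unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    yates <- chi_square_2x2(tab, correct = TRUE)
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(yates$chi_square_statistic, unname(ref_y$statistic),
                 tolerance = 1e-10)
    # symmetry under row and column swaps
    expect_equal(chi_square_2x2(tab[2:1, ])$chi_square_statistic,
                 ours$chi_square_statistic)
    expect_equal(chi_square_2x2(tab[, 2:1])$chi_square_statistic,
                 ours$chi_square_statistic)
  }

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginals")
})
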
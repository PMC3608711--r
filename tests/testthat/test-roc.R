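test_that("empirical ROC matches exhaustive pair counting", {
  # pos {3,5}, neg {1,4}: concordant pairs 3/4 -> AUC 0.75
  rc <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc$auc, 0.75)
  expect_equal(rc$n_pos, 2)
  expect_equal(rc$n_neg, 2)
  # curve shape contract along increasing thresholds
  expect_true(all(diff(rc$sensitivity) <= 0))
  expect_true(all(diff(rc$specificity) >= 0))
  expect_true(is.infinite(tail(rc$thresholds, 1)))

  # perfect separation and a permuted null
  expect_equal(roc_curve(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(5)
  null_auc <- roc_curve(rnorm(4000), rep(c(TRUE, FALSE), 2000))$auc
  expect_equal(null_auc, 0.5, tolerance = 0.05)
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  auc_mw <- function(scores, labels) {
    r <- rank(scores)
    m <- sum(labels); n <- sum(!labels)
    (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
  }
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    rc <- roc_curve(scores, labels)
    expect_equal(rc$auc, auc_mw(scores, labels), tolerance = 1e-12)
    # orientation flip maps AUC -> 1 - AUC
    rc2 <- roc_curve(scores, labels, "less_is_diseased")
    expect_equal(rc2$auc, 1 - rc$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- round(rnorm(300), 1)
  labels <- runif(300) < 0.5
  rc <- roc_curve(scores, labels)
  pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(rc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("DeLong comparison: self-test, degenerate variance, pROC check", {
  set.seed(21)
  labels <- rep(c(TRUE, FALSE), each = 25)
  a <- rnorm(50) + labels
  # marker compared with itself: z = 0, p = 1
  d0 <- delong_compare(a, a, labels)
  expect_equal(d0$z, 0)
  expect_equal(d0$p_value, 1)
  # independent oracle: pROC's implementation of the same test
  skip_if_not_installed("pROC")
  b <- rnorm(50) + 0.5 * labels
  d <- delong_compare(a, b, labels)
  pr <- pROC::roc.test(
    pROC::roc(labels, a, direction = "<", quiet = TRUE),
    pROC::roc(labels, b, direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(d$p_value, pr$p.value, tolerance = 1e-9)
  expect_equal(d$auc_a, as.numeric(pr$estimate[1]), tolerance = 1e-12)
  expect_equal(d$auc_b, as.numeric(pr$estimate[2]), tolerance = 1e-12)
})

test_that("Youden cutoff with specificity tie-break and gap midpoints", {
  # pos {3,5}, neg {1,4}: J maximized on (4,5], tie broken to higher
  # specificity -> cutoff 4.5 (exhaustive-threshold oracle)
  rc <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  j_oracle <- function(t) mean(c(3, 5) >= t) + mean(c(1, 4) < t) - 1
  expect_equal(max(sapply(seq(0, 6, 0.01), j_oracle)), 0.5)
  expect_equal(optimal_cutoff(rc), 4.5)
  expect_equal(j_oracle(optimal_cutoff(rc)), 0.5)
  # separated classes: midpoint of the gap
  rc2 <- roc_curve(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(optimal_cutoff(rc2), 5)
  # less_is_diseased orientation reports on the original scale
  rc3 <- roc_curve(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE),
                   "less_is_diseased")
  expect_equal(optimal_cutoff(rc3), 5)
})

test_that("sensitivity at fixed specificity uses the smallest qualifying
           threshold", {
  rc <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sensitivity_at_specificity(rc, 0.75), 0.5)
  rc2 <- roc_curve(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sensitivity_at_specificity(rc2, 0.9), 1)
  # interpolated variant lies between the bracketing points
  si <- sensitivity_at_specificity(rc, 0.75, interpolate = TRUE)
  expect_gte(si, 0.5)
  expect_lte(si, 1)
})

test_that("single-class input errors", {
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
  expect_error(delong_compare(1:4, 4:1, rep(FALSE, 4)), "both classes")
})

test_that("published cutoff and control-IQR presets are exposed", {
  expect_equal(cutoff_preset("table1", "S"), 7.00)
  expect_equal(cutoff_preset("table1", "T"), 1.087)
  expect_equal(cutoff_preset("table1", "V"), 0.715)
  expect_equal(cutoff_preset("control_iqr", "S"), 7.2)
})
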
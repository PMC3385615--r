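test_that("confusion rates reproduce the published performance cells", {
  # balanced 31/31 cohort, 26 correct in each group
  m1 <- confusion_metrics(confusion_counts(tp = 26, fp = 5, fn = 5, tn = 26))
  expect_equal(m1$sensitivity, 26 / 31)
  expect_equal(m1$specificity, 26 / 31)
  expect_equal(m1$accuracy, 52 / 62)
  expect_equal(round(m1$accuracy, 3), 0.839)

  m2 <- confusion_metrics(confusion_counts(tp = 26, fp = 1, fn = 5, tn = 30))
  expect_equal(m2$accuracy, 56 / 62)
  expect_equal(round(m2$accuracy, 3), 0.903)
  expect_equal(round(m2$ppv, 3), 0.963)
  expect_equal(round(m2$npv, 3), 0.857)

  perfect <- confusion_metrics(confusion_counts(31, 0, 0, 31))
  expect_true(all(unlist(perfect) == 1))
})

test_that("undefined rates are NA with a warning, empty matrices error", {
  expect_warning(m <- confusion_metrics(confusion_counts(0, 0, 5, 5)), "PPV")
  expect_true(is.na(m$ppv))
  expect_error(confusion_counts(0, 0, 0, 0), "empty-input")
  expect_error(confusion_counts(-1, 0, 0, 2), "non-negative")
})

test_that("Cohen's kappa matches the published agreement values", {
  expect_equal(round(cohen_kappa(confusion_counts(26, 5, 5, 26)), 3), 0.677)
  expect_equal(round(cohen_kappa(confusion_counts(27, 3, 4, 28)), 3), 0.774)
  expect_equal(round(cohen_kappa(confusion_counts(26, 1, 5, 30)), 3), 0.806)
  expect_equal(cohen_kappa(confusion_counts(31, 0, 0, 31)), 1)
  # agreement exactly at chance
  expect_equal(cohen_kappa(confusion_counts(5, 5, 5, 5)), 0)
})

test_that("kappa equals 2*accuracy - 1 for balanced true groups", {
  withr::local_seed(41)
  for (i in 1:50) {
    n <- sample(2:60, 1)
    tp <- sample(0:n, 1)
    fp <- sample(0:n, 1)
    cm <- confusion_counts(tp, fp, n - tp, n - fp)
    acc <- suppressWarnings(confusion_metrics(cm)$accuracy)  # extreme matrices
    expect_equal(cohen_kappa(cm), 2 * acc - 1, tolerance = 1e-12)
  }
})

test_that("ROC handles perfect separation, interleaving and identical groups", {
  expect_equal(roc_curve(c(3, 4), c(1, 2))$auc, 1)
  expect_equal(roc_curve(c(2, 4), c(1, 3))$auc, 0.75)  # 4-pair enumeration
  expect_equal(roc_curve(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_error(roc_curve(numeric(0), 1), "empty-group")
})

test_that("trapezoidal AUC equals the pair-counting estimator on random scores", {
  withr::local_seed(43)
  for (i in 1:50) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    # mix continuous and tied integer scores
    if (i %% 2 == 0) {
      norm <- rnorm(n1, 1, 1); abn <- rnorm(n2, 0, 1)
    } else {
      norm <- sample(0:8, n1, replace = TRUE); abn <- sample(0:8, n2, replace = TRUE)
    }
    roc <- roc_curve(norm, abn)
    expect_equal(roc$auc, oracle_auc(norm, abn), tolerance = 1e-12,
                 info = paste("instance", i))
    # sensitivity non-decreasing in the threshold
    expect_true(all(diff(roc$points$sensitivity) >= 0))
  }
})

test_that("swapping group labels maps auc to 1 - auc", {
  withr::local_seed(47)
  norm <- rnorm(15, 1); abn <- rnorm(20, 0)
  expect_equal(roc_curve(abn, norm)$auc, 1 - roc_curve(norm, abn)$auc,
               tolerance = 1e-12)
})

test_that("the operating point maximizes Youden's J with low tie-break", {
  # abnormal {1,3} vs normal {2,4}: J = 0.5 at t = 1 and t = 3; tie broken low
  roc <- roc_curve(c(2, 4), c(1, 3))
  expect_equal(convex_point(roc), 1)
  # perfect separation: smallest threshold attaining J = 1 is the largest
  # abnormal score
  roc2 <- roc_curve(c(10, 11), c(1, 2))
  expect_equal(convex_point(roc2), 2)
  # exhaustive check on a random instance
  withr::local_seed(53)
  norm <- round(rnorm(20, 2), 1); abn <- round(rnorm(20, 0), 1)
  roc3 <- roc_curve(norm, abn)
  thr <- sort(unique(c(norm, abn)))
  j <- vapply(thr, function(t) mean(abn <= t) + mean(norm > t) - 1, numeric(1))
  expect_equal(convex_point(roc3), thr[which.max(j)])
  # closest-topleft rule returns a finite threshold too
  expect_true(is.finite(convex_point(roc3, rule = "closest_topleft")))
})

test_that("AUC significance behaves at the chance and separation extremes", {
  expect_equal(auc_significance(0.5, 31, 31), 1)
  expect_lt(auc_significance(1, 31, 31), 1e-6)
  # monotone in the AUC
  p_high <- auc_significance(0.94, 31, 31)
  p_low <- auc_significance(0.7, 31, 31)
  expect_lt(p_high, 0.001)  # published AUCs above 0.93 are all significant
  expect_lt(p_high, p_low)
  expect_error(auc_significance(0.8, 1, 31), "sizes")
})

test_that("pooled t-test reproduces the published Mean-feature p-value", {
  res <- two_sample_t(list(mean = 0.865, sd = 0.164, n = 31),
                      list(mean = 0.410, sd = 0.203, n = 31))
  expect_equal(res$df, 60)
  expect_equal(res$p, 6.82e-14, tolerance = 0.25)  # inputs printed to 3 decimals
})

test_that("summary-statistic t-test agrees with stats::t.test on raw samples", {
  withr::local_seed(59)
  x <- rnorm(25, 1, 2); y <- rnorm(18, 0, 1.5)
  pooled <- two_sample_t(x, y, variant = "pooled")
  ref_p <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref_p$statistic), tolerance = 1e-12)
  expect_equal(pooled$p, ref_p$p.value, tolerance = 1e-12)
  welch <- two_sample_t(x, y, variant = "welch")
  ref_w <- stats::t.test(x, y)
  expect_equal(welch$t, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-9)
  expect_equal(welch$p, ref_w$p.value, tolerance = 1e-12)
})

test_that("t-test degenerate contracts hold", {
  expect_equal(two_sample_t(list(mean = 1, sd = 1, n = 10),
                            list(mean = 1, sd = 1, n = 10))$p, 1)
  expect_error(two_sample_t(list(mean = 1, sd = 0, n = 5),
                            list(mean = 1, sd = 0, n = 5)), "undefined-t")
  expect_error(two_sample_t(list(mean = 1, sd = 1, n = 1),
                            list(mean = 0, sd = 1, n = 5)), "n >= 2")
})

test_that("t-test maintains its nominal type-I error on null simulations", {
  withr::local_seed(61)
  reps <- 400
  p <- replicate(reps, {
    two_sample_t(rnorm(15), rnorm(15))$p
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("95% CIs reproduce every printed group interval to 3 decimals", {
  rows <- list(
    list(29.419, 8.398, 31, 26.339, 32.500),   # age, normal
    list(56.000, 10.724, 31, 52.066, 59.934),  # age, abnormal
    list(67.161, 13.518, 31, 62.203, 72.120),  # weight, normal
    list(65.452, 13.112, 31, 60.642, 70.261),  # weight, abnormal
    list(0.356, 0.047, 31, 0.339, 0.373),      # entropy, normal
    list(0.233, 0.077, 31, 0.205, 0.262),      # entropy, abnormal
    list(0.865, 0.164, 31, 0.804, 0.925),      # mean, normal
    list(0.410, 0.203, 31, 0.335, 0.484),      # mean, abnormal
    list(3.253, 0.456, 31, 3.086, 3.421),      # sd, normal
    list(1.969, 0.753, 31, 1.693, 2.245)       # sd, abnormal
  )
  for (r in rows) {
    ci <- ci95(r[[1]], r[[2]], r[[3]])
    expect_lt(abs(ci$ci_low - r[[4]]), 1.5e-3)
    expect_lt(abs(ci$ci_high - r[[5]]), 1.5e-3)
  }
  expect_equal(ci95(2, 0, 5), tibble::tibble(ci_low = 2, ci_high = 2))
  expect_error(ci95(1, 1, 1), "insufficient-n")
})
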
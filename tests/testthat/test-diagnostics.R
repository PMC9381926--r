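test_that("Bland-Altman identities hold", {
  co <- generate_cohort(cohort_config(seed = 23))
  a <- la_alpha(co$vE, co$vS, co$vD)
  cal <- fit_calibration(a, co$pawp_mmHg)
  # back-calculation from the same-cohort inverted OLS: bias is exactly zero
  ba <- bland_altman(co$pawp_mmHg, predict_pawp(cal, a))
  expect_equal(ba$bias, 0, tolerance = 1e-10)
  expect_lt(ba$loa_low, ba$loa_high)
  # a constant offset moves the bias and leaves the scatter unchanged
  ba3 <- bland_altman(co$pawp_mmHg + 3, predict_pawp(cal, a))
  expect_equal(ba3$bias, 3, tolerance = 1e-10)
  expect_equal(ba3$sd_diff, ba$sd_diff, tolerance = 1e-12)
  expect_error(bland_altman(1:5, 1:4), "equal length")
})

test_that("the SD of differences equals the inverse-scaled alpha residual scatter", {
  co <- generate_cohort(cohort_config(seed = 24))
  a <- la_alpha(co$vE, co$vS, co$vD)
  cal <- fit_calibration(a, co$pawp_mmHg)
  ba <- bland_altman(co$pawp_mmHg, predict_pawp(cal, a))
  # oracle: differences are -resid_alpha / slope, so their sample SD is
  # sd(resid) / slope exactly
  expect_equal(ba$sd_diff, sd(resid(cal$model)) / cal$slope_b,
               tolerance = 1e-10)
})

test_that("empirical AUC equals exhaustive pair counting on tied fixtures", {
  set.seed(25)
  for (rep in 1:20) {
    scores <- round(runif(20, 0, 4), 1)  # rounding induces ties
    labels <- runif(20) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, auc_pairs(scores, labels), tolerance = 1e-12)
    # swapped labels invert the AUC
    r2 <- roc_analysis(scores, !labels)
    expect_equal(r2$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 with the Youden cut-off between classes", {
  scores <- c(1, 1.2, 1.5, 2.8, 3, 3.3)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, 1)
  expect_gt(r$youden$cutoff, 1.5)
  expect_lt(r$youden$cutoff, 2.8)
  expect_equal(r$youden$sensitivity, 1)
  expect_equal(r$youden$specificity, 1)
})

test_that("the Youden cut-off maximizes sensitivity + specificity over all thresholds", {
  co <- generate_cohort(cohort_config(seed = 26))
  a <- la_alpha(co$vE, co$vS, co$vD)
  pos <- co$pawp_mmHg > 15
  r <- roc_analysis(a, pos)
  ysum <- r$points$sensitivity + r$points$specificity
  expect_equal(r$youden$sensitivity + r$youden$specificity, max(ysum),
               tolerance = 1e-12)
  # lowest maximizing threshold wins a tie
  expect_equal(r$youden$cutoff, min(r$points$threshold[ysum == max(ysum)]))
  # ROC curve is monotone in the threshold sweep
  expect_true(all(diff(r$points$sensitivity) <= 1e-12))
  expect_true(all(diff(r$points$specificity) >= -1e-12))
})

test_that("the regression cut-off reproduces the PAWP_calc > threshold rule exactly", {
  co <- generate_cohort(cohort_config(seed = 27))
  a <- la_alpha(co$vE, co$vS, co$vD)
  cal <- fit_calibration(a, co$pawp_mmHg)
  r <- roc_analysis(a, co$pawp_mmHg > 15, calibration = cal)
  rule_alpha <- a > r$regression$cutoff
  rule_pawp <- predict_pawp(cal, a) > 15
  expect_identical(rule_alpha, rule_pawp)
})

test_that("AUC confidence interval brackets the point estimate and matches pROC", {
  co <- generate_cohort(cohort_config(seed = 28))
  a <- la_alpha(co$vE, co$vS, co$vD)
  pos <- co$pawp_mmHg > 15
  r <- roc_analysis(a, pos)
  expect_lte(r$ci95_auc[1], r$auc)
  expect_gte(r$ci95_auc[2], r$auc)
  # independent cross-check of the point estimate
  proc_auc <- as.numeric(pROC::auc(pROC::roc(pos, a, quiet = TRUE,
                                             direction = "<",
                                             levels = c(FALSE, TRUE))))
  expect_equal(r$auc, proc_auc, tolerance = 1e-12)
  expect_error(roc_analysis(a, rep(TRUE, length(a))), "both classes")
})

test_that("sensitivity and specificity carry exact binomial confidence intervals", {
  scores <- c(rep(1, 6), rep(3, 14))
  labels <- rep(c(FALSE, TRUE), c(6, 14))
  r <- roc_analysis(scores, labels)
  y <- r$youden
  expect_equal(y$sens_ci,
               as.numeric(binom.test(14, 14)$conf.int), tolerance = 1e-12)
  expect_equal(y$spec_ci,
               as.numeric(binom.test(6, 6)$conf.int), tolerance = 1e-12)
})
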
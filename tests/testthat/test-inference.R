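test_that("calibration interpolates exact collinear data and inverts correctly", {
  cal <- fit_calibration(c(0.5, 1.5, 2.5), c(0, 10, 20))
  expect_equal(cal$intercept_a, 0.5, tolerance = 1e-12)
  expect_equal(cal$slope_b, 0.10, tolerance = 1e-12)
  expect_equal(cal$inverse_intercept, -5, tolerance = 1e-10)
  expect_equal(cal$inverse_slope, 10, tolerance = 1e-10)
  expect_equal(predict_pawp(cal, 2.10), 16, tolerance = 1e-9)
  expect_error(fit_calibration(c(1, 2, 3), c(5, 5, 5)), "variance")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3")
})

test_that("PRESS equals explicit leave-one-out refits", {
  co <- generate_cohort(small_config(seed = 10))
  cal <- fit_calibration(
    la_alpha(co$vE, co$vS, co$vD), co$pawp_mmHg)
  a <- la_alpha(co$vE, co$vS, co$vD); p <- co$pawp_mmHg
  # brute-force oracle: refit without record i, predict alpha_i
  press <- sum(vapply(seq_along(a), function(i) {
    m <- lm(a[-i] ~ p[-i])
    (a[i] - (coef(m)[1] + coef(m)[2] * p[i]))^2
  }, numeric(1)))
  expect_equal(1 - press / sum((a - mean(a))^2), cal$press_r2,
               tolerance = 1e-10)
  expect_lte(cal$press_r2, cal$r^2)
})

test_that("identical groups give F ~ 0 and Tukey p ~ 1", {
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  cmp <- compare_groups(v, g)
  expect_lt(cmp$anova_F, 1e-10)
  expect_true(all(cmp$tukey$p_adj > 0.999))
  expect_equal(nrow(cmp$tukey), 3)  # all three pairs
})

test_that("two-group Tukey-Kramer matches the studentized-range t equivalence", {
  set.seed(14)
  v <- c(rnorm(8, 0), rnorm(12, 1))
  g <- rep(c("a", "b"), c(8, 12))
  cmp <- compare_groups(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  # oracle: q = |t| * sqrt(2) on the pooled df
  p_oracle <- ptukey(abs(tt$statistic) * sqrt(2), 2, 18, lower.tail = FALSE)
  expect_equal(cmp$tukey$p_adj, unname(p_oracle), tolerance = 1e-8)
  expect_equal(cmp$tukey$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("group comparison tolerates a zero-variance group", {
  v <- c(rep(5, 3), rnorm(5, 6), rnorm(4, 9))
  g <- rep(c("a", "b", "c"), c(3, 5, 4))
  expect_no_error(cmp <- compare_groups(v, g))
  expect_true(is.finite(cmp$anova_F))
})

test_that("partial F-test matches the anova() oracle and rejects bad inputs", {
  set.seed(15)
  d <- data.frame(x = rnorm(10), z = rnorm(10), b = rep(0:1, 5))
  d$y <- 1 + 2 * d$x + 0.5 * d$z + rnorm(10, 0, 0.3)
  base <- lm(y ~ x, data = d)
  for (full in list(lm(y ~ x + z, data = d),
                    lm(y ~ x + b, data = d),
                    lm(y ~ x * b, data = d))) {
    res <- partial_f_test(base, full)
    oracle <- anova(base, full)
    expect_equal(res$F, oracle$F[2], tolerance = 1e-10)
    expect_equal(res$p, oracle$`Pr(>F)`[2], tolerance = 1e-10)
  }
  d$x2 <- d$x
  expect_error(partial_f_test(base, lm(y ~ x + x2, data = d)),
               "rank deficient")
  expect_error(partial_f_test(base, lm(y ~ z, data = d)), "nested")
  # a term orthogonal to the base-model residuals explains nothing: F ~ 0
  d$w <- rnorm(10); d$rb <- resid(base)
  d$orth <- resid(lm(w ~ x + rb, data = d))
  res0 <- partial_f_test(base, lm(y ~ x + orth, data = d))
  expect_lt(res0$F, 1e-18)
})

test_that("Williams-Hotelling is null for identical correlates and matches a permutation oracle", {
  set.seed(16)
  x <- rnorm(20); y <- x + rnorm(20)
  res <- compare_dependent_correlations(x, y, y)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  # permutation oracle: with equal noise scales (y, z) are exchangeable
  # within pairs under H0, so swapping the y/z assignment generates the
  # null distribution of the statistic. A single n = 20 fixture can put
  # the two p-values ~0.2 apart (the tests condition differently), so the
  # comparison runs across fixtures.
  set.seed(17)
  ps <- replicate(25, {
    x <- rnorm(20); y <- x + rnorm(20); z <- x + rnorm(20)
    obs <- compare_dependent_correlations(x, y, z)
    tperm <- replicate(300, {
      sw <- runif(20) < 0.5
      compare_dependent_correlations(x, ifelse(sw, z, y),
                                     ifelse(sw, y, z))$t_statistic
    })
    c(w = obs$p_value, perm = mean(abs(tperm) >= abs(obs$t_statistic)))
  })
  expect_lt(mean(abs(ps["w", ] - ps["perm", ])), 0.1)
  expect_lt(abs(mean(ps["w", ]) - mean(ps["perm", ])), 0.06)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(compare_dependent_correlations(rnorm(10), y[1:10], -y[1:10]),
               "degenerate")
})

test_that("one-sample t matches the published location-bias arithmetic", {
  # mean 6, SD 9, n = 56: t = 6 / (9 / sqrt(56)) ~ 4.99, p < 1e-4
  set.seed(18)
  d <- rnorm(56)
  d <- 6 + 9 * (d - mean(d)) / sd(d)
  res <- one_sample_t(d)
  expect_equal(res$t, 6 / (9 / sqrt(56)), tolerance = 1e-12)
  expect_lt(res$p, 1e-4)
  # symmetry and degenerate cases
  expect_equal(one_sample_t(-d)$t, -res$t, tolerance = 1e-12)
  expect_equal(one_sample_t(rep(0, 5))[c("t", "p")], list(t = 0, p = 1))
  expect_equal(one_sample_t(rep(2, 5))[c("t", "p")], list(t = Inf, p = 0))
})

test_that("noise-free cohorts recover the defining ratio exactly", {
  co <- generate_cohort(cohort_config(seed = 19, alpha_noise_sd = 0))
  fit <- fit_general_ratio(co)
  expect_equal(fit$c_out, 1, tolerance = 1e-4)
  expect_equal(fit$c_in, 0, tolerance = 1e-4)
  expect_equal(fit$r_nonlinear, 1, tolerance = 1e-6)
  ff <- fit_general_ratio(co, fix_c_out = 1)
  expect_equal(ff$c_in, 0, tolerance = 1e-4)
  expect_equal(ff$r_nonlinear, 1, tolerance = 1e-6)
})

test_that("the general-ratio fit nests the linear calibration at its optimum", {
  co <- generate_cohort(cohort_config(seed = 20))
  fit <- fit_general_ratio(co)
  d <- co[!is.na(co$vA), ]
  ag <- alpha_general(d$vE, d$vA, d$vS, d$vD, fit$c_out, fit$c_in)
  ols <- lm(d$pawp_mmHg ~ ag)
  # with (c_out, c_in) frozen at the optimum the fit is exactly OLS on
  # the computed ratio values
  expect_equal(unname(coef(ols)), c(fit$beta0, fit$beta1), tolerance = 1e-6)
  expect_equal(summary(ols)$r.squared, fit$r_nonlinear^2, tolerance = 1e-8)
  # and on default cohorts it certifies (1, 0) as the optimal choice
  expect_true(fit$optimal)
  expect_lte(fit$n_used, nrow(co))
})

test_that("the fixed-c_out fit admits monophasic records", {
  co <- generate_cohort(cohort_config(seed = 22))
  expect_gt(sum(is.na(co$vA)), 0)
  ff <- fit_general_ratio(co, fix_c_out = 1)
  expect_equal(ff$n_used, nrow(co))  # all patients enter
  free <- fit_general_ratio(co)
  expect_equal(free$n_used, sum(!is.na(co$vA)))  # biphasic only
})
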
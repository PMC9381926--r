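test_that("default cohort reproduces the published group structure and is seed-deterministic", {
  co <- generate_cohort(cohort_config(seed = 11))
  expect_s3_class(co, "la_cohort")
  expect_equal(nrow(co), 62)
  expect_equal(as.integer(table(co$group)[c("non_PH", "pre_capillary_PH",
                                            "post_capillary_PH")]),
               c(28L, 21L, 13L))
  vel <- c("vS", "vD", "vE", "vS_vein", "vD_vein", "vE_tip")
  expect_true(all(as.matrix(co[vel]) > 0))
  expect_true(all(co$vA[!is.na(co$vA)] > 0))
  # v_A and v_A,tip missing exactly for the monophasic subset
  expect_identical(is.na(co$vA), is.na(co$vA_tip))
  # post-capillary label coincides with PAWP > 15 mmHg by construction
  expect_identical(co$pawp_mmHg > 15, co$group == "post_capillary_PH")

  co2 <- generate_cohort(cohort_config(seed = 11))
  expect_identical(co, co2)
  co3 <- generate_cohort(cohort_config(seed = 12))
  expect_false(identical(co$pawp_mmHg, co3$pawp_mmHg))

  # byte-identical CSV under the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f1); write_cohort_csv(co2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_cohort_csv(f1)
  expect_equal(back$pawp_mmHg, co$pawp_mmHg, tolerance = 1e-6)
  expect_identical(is.na(back$vA), is.na(co$vA))
})

test_that("noise-free degenerate law makes alpha exactly the intercept", {
  cfg <- small_config(seed = 4)
  cfg$alpha_noise_sd <- 0
  cfg$alpha_slope <- 1e-12  # slope must be positive; effectively zero
  co <- generate_cohort(cfg)
  expect_equal(la_alpha(co$vE, co$vS, co$vD),
               rep(cfg$alpha_intercept, nrow(co)), tolerance = 1e-9)

  # with the default slope and zero noise the law holds exactly per record
  cfg2 <- cohort_config(seed = 4, alpha_noise_sd = 0)
  co2 <- generate_cohort(cfg2)
  expect_equal(la_alpha(co2$vE, co2$vS, co2$vD),
               0.61 + 0.10 * co2$pawp_mmHg, tolerance = 1e-12)
})

test_that("pooled PAWP moments match the truncated-normal mixture computed numerically", {
  # independent oracle: numeric integration of the three truncated normals
  tn <- function(mu, sd, lo, hi) {
    z <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
    m1 <- integrate(function(x) x * dnorm(x, mu, sd) / z, lo, hi)$value
    m2 <- integrate(function(x) x^2 * dnorm(x, mu, sd) / z, lo, hi)$value
    c(m1, m2 - m1^2)
  }
  g <- lapply(default_groups(), function(s)
    c(s$n, tn(s$pawp_mean, s$pawp_sd, s$pawp_lo, s$pawp_hi)))
  w <- vapply(g, `[`, numeric(1), 1) / 62
  mix_mean <- sum(w * vapply(g, `[`, numeric(1), 2))
  mix_var <- sum(w * (vapply(g, `[`, numeric(1), 3) +
                        vapply(g, `[`, numeric(1), 2)^2)) - mix_mean^2
  # the design anchors: mixture SD close to the printed cohort SD of ~5.4
  expect_lt(abs(sqrt(mix_var) - 5.4) / 5.4, 0.10)

  set.seed(21)
  seeds <- sample.int(1e7, 400)
  pawp <- unlist(lapply(seeds, function(s)
    generate_cohort(cohort_config(seed = s))$pawp_mmHg))
  se <- sqrt(mix_var / length(pawp))
  expect_lt(abs(mean(pawp) - mix_mean), 3 * se)
  expect_lt(abs(sd(pawp) - sqrt(mix_var)) / sqrt(mix_var), 0.10)
})

test_that("velocity correlation structure matches the configured targets", {
  set.seed(8)
  seeds <- sample.int(1e7, 200)
  cos <- lapply(seeds, function(s) generate_cohort(cohort_config(seed = s)))
  # within-group corr(vS, vD) near the configured 0.38
  by_group <- function(co, f) {
    mean(vapply(split(co, co$group), f, numeric(1)))
  }
  r_sd <- mean(vapply(cos, function(co)
    by_group(co, function(d) cor(d$vS, d$vD)), numeric(1)))
  expect_lt(abs(r_sd - 0.38), 0.10)
  # latent-factor-induced corr(vS, vA) near the configured 0.58
  r_sa <- mean(vapply(cos, function(co)
    by_group(co, function(d) cor(d$vS, d$vA, use = "complete.obs")),
    numeric(1)))
  expect_lt(abs(r_sa - 0.58), 0.10)
  # monophasic count behaves like Binomial(62, 6/62): mean ~ 6
  mono <- vapply(cos, function(co) sum(is.na(co$vA)), numeric(1))
  expect_lt(abs(mean(mono) - 6), 3 * sqrt(6 * (1 - 6 / 62) / length(cos)))
})

test_that("alternative-location velocities reproduce the published biases", {
  set.seed(31)
  seeds <- sample.int(1e7, 150)
  bias <- vapply(seeds, function(s) {
    co <- generate_cohort(cohort_config(seed = s))
    c(mean(co$vE_tip - co$vE), sd(co$vE_tip - co$vE),
      mean(co$vS_vein - co$vS))
  }, numeric(3))
  expect_lt(abs(mean(bias[1, ]) - 6), 1)    # vE,tip bias ~ +6 cm/s
  expect_lt(abs(mean(bias[2, ]) - 9), 1.5)  # its SD ~ 9 cm/s
  expect_lt(abs(mean(bias[3, ]) - 1), 1)    # vS,vein bias ~ +1 cm/s
})

test_that("impossible velocity moments fail after bounded retries", {
  g <- default_groups()
  g[[1]]$vS_mean <- -200; g[[1]]$vS_sd <- 0.1
  cfg <- cohort_config(groups = g, seed = 1, max_retries = 20)
  expect_error(generate_cohort(cfg), "retries")
})
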
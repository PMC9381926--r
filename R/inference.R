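#' Fit the general velocity-ratio model for PAWP
#'
#' Least-squares fit of `PAWP = b0 + b1 * alpha_general(c_out, c_in)` over
#' a cohort, treating `(b0, b1, c_out, c_in)` as free parameters. This is
#' the model-selection step that motivates the acceleration factor: the
#' specific ratio is judged optimal when `c_out = 1` and `c_in = 0` fall
#' inside the large-sample 95% confidence intervals of the fit. With
#' `fix_c_out = 1` the numerator reduces to `v_E`, `v_A` drops out, and
#' all patients (including monophasic profiles) enter the fit.
#'
#' The optimiser is Levenberg-Marquardt least squares with a multi-start
#' over a small `(c_out, c_in)` grid; the reported fit is the converged
#' start with the lowest residual sum of squares. Confidence intervals are
#' Wald intervals from the asymptotic covariance `s^2 (J'J)^-1` at the
#' optimum, on `n - 4` degrees of freedom (`n - 3` when `c_out` is fixed).
#' The non-linear correlation coefficient is `sqrt(1 - SSE/SST)`.
#'
#' @param cohort Cohort data frame with `pawp_mmHg`, `vE`, `vA`, `vS`, `vD`.
#' @param fix_c_out Optional fixed value for `c_out` (typically 1).
#' @param starts Data frame of starting values for `c_out`, `c_in`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An `la_ratio_fit` list: `beta0`, `beta1`, `c_out`, `c_in`, the
#'   CI matrix `ci` (rows `c_out`, `c_in`), `r_nonlinear`, `sse`, `n_used`,
#'   `df`, `converged`, and `optimal` (are the defining choices
#'   `c_out = 1`, `c_in = 0` inside their CIs).
#' @export
fit_general_ratio <- function(cohort, fix_c_out = NULL,
                              starts = expand.grid(c_out = c(0, 0.5, 1),
                                                   c_in = c(-0.5, 0, 0.5, 1)),
                              conf_level = 0.95) {
  free_c_out <- is.null(fix_c_out)
  d <- cohort
  if (free_c_out) d <- d[!is.na(d$vA), , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("pawp_mmHg", "vS", "vD", "vE")]), ,
         drop = FALSE]
  n <- nrow(d)
  if (free_c_out && n < 10)
    stop("need >= 10 biphasic records to fit c_out freely", call. = FALSE)
  if (!free_c_out && n < 5)
    stop("too few records for the fixed-c_out fit", call. = FALSE)

  d$vSplusD <- (d$vS + d$vD) / 2
  d$vSminusD <- (d$vS - d$vD) / 2
  if (free_c_out) {
    d$vEplusA <- (d$vE + d$vA) / 2
    d$vEminusA <- (d$vE - d$vA) / 2
    form <- pawp_mmHg ~ b0 + b1 * (vEplusA + c_out * vEminusA) /
      (vSplusD + c_in * vSminusD)
  } else {
    form <- pawp_mmHg ~ b0 + b1 * vE / (vSplusD + c_in * vSminusD)
  }

  ols0 <- stats::lm(d$pawp_mmHg ~ I(d$vE / d$vSplusD))
  b_start <- stats::coef(ols0)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(b0 = unname(b_start[1]), b1 = unname(b_start[2]),
               c_in = starts$c_in[i])
    if (free_c_out) st$c_out <- starts$c_out[i]
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = d, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (!all(is.finite(stats::coef(fit))) || !is.finite(sse)) next
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("general-ratio fit failed to converge from any start; check ",
         "denominator positivity of the data", call. = FALSE)

  fit <- best$fit
  cf <- stats::coef(fit)
  p <- length(cf)
  df <- n - p
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, p, p,
    dimnames = list(names(cf), names(cf))))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  ci_of <- function(par) {
    if (!par %in% names(cf)) return(c(NA_real_, NA_real_))
    se <- sqrt(vc[par, par])
    cf[par] + c(-1, 1) * tq * se
  }
  ci <- rbind(c_out = ci_of("c_out"), c_in = ci_of("c_in"))
  colnames(ci) <- c("lo", "hi")
  sst <- sum((d$pawp_mmHg - mean(d$pawp_mmHg))^2)
  r_nl <- sqrt(max(0, 1 - best$sse / sst))
  c_out_hat <- if (free_c_out) unname(cf["c_out"]) else fix_c_out
  optimal <- (!free_c_out || (ci["c_out", 1] <= 1 && 1 <= ci["c_out", 2])) &&
    (ci["c_in", 1] <= 0 && 0 <= ci["c_in", 2])
  structure(list(beta0 = unname(cf["b0"]), beta1 = unname(cf["b1"]),
                 c_out = c_out_hat, c_in = unname(cf["c_in"]),
                 ci = ci, r_nonlinear = r_nl, sse = best$sse,
                 n_used = n, df = df, converged = TRUE, optimal = optimal,
                 fit = fit),
            class = "la_ratio_fit")
}

#' Linear calibration of the acceleration factor against PAWP
#'
#' Ordinary least squares of `alpha` on PAWP, `alpha = a + b * PAWP`, with
#' the leave-one-out PRESS R-squared (computed by the hat-matrix shortcut,
#' so no refits are needed) and the inverted law
#' `PAWP_calc = -a/b + (1/b) * alpha` used to estimate pressure from flow.
#'
#' @param alpha Acceleration factors.
#' @param pawp PAWP values, mmHg.
#' @return An `la_calibration` list: `intercept_a`, `slope_b`, `r`,
#'   `rmse` (residual SE of alpha on `n - 2` df), `press_r2`,
#'   `inverse_intercept`, `inverse_slope`, `n`, and the underlying `lm`.
#' @export
fit_calibration <- function(alpha, pawp) {
  ok <- is.finite(alpha) & is.finite(pawp)
  alpha <- alpha[ok]; pawp <- pawp[ok]
  n <- length(alpha)
  if (n < 3) stop("need at least 3 complete (alpha, PAWP) pairs",
                  call. = FALSE)
  if (stats::var(pawp) == 0) stop("PAWP has zero variance", call. = FALSE)
  m <- stats::lm(alpha ~ pawp)
  a <- unname(stats::coef(m)[1]); b <- unname(stats::coef(m)[2])
  res <- stats::resid(m)
  h <- stats::lm.influence(m, do.coef = FALSE)$hat
  press <- sum((res / (1 - h))^2)
  sst <- sum((alpha - mean(alpha))^2)
  structure(list(intercept_a = a, slope_b = b,
                 r = stats::cor(alpha, pawp),
                 rmse = sqrt(sum(res^2) / (n - 2)),
                 press_r2 = 1 - press / sst,
                 inverse_intercept = -a / b, inverse_slope = 1 / b,
                 n = n, model = m),
            class = "la_calibration")
}

#' Back-calculate PAWP from the acceleration factor
#'
#' @param cal An `la_calibration`.
#' @param alpha Acceleration factor value(s).
#' @return Estimated PAWP, mmHg.
#' @export
predict_pawp <- function(cal, alpha) {
  stopifnot(inherits(cal, "la_calibration"))
  cal$inverse_intercept + cal$inverse_slope * alpha
}

#' Compare a parameter across the diagnostic groups
#'
#' One-way ANOVA with Tukey-Kramer pairwise comparisons (the studentized
#' range procedure for unequal group sizes, as provided by
#' [stats::TukeyHSD()]).
#'
#' @param values Numeric vector.
#' @param labels Group labels (coerced to factor).
#' @return An `la_group_comparison` list: per-group `summary` (n, mean,
#'   sd), `anova_F`, `anova_p`, and `tukey` (pairwise differences with
#'   adjusted p-values).
#' @export
compare_groups <- function(values, labels) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(labels[ok])
  stopifnot(nlevels(labels) >= 2, all(table(labels) >= 2))
  smry <- do.call(rbind, lapply(levels(labels), function(l) {
    v <- values[labels == l]
    data.frame(group = l, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  fit <- stats::aov(values ~ labels)
  at <- summary(fit)[[1]]
  tk <- as.data.frame(stats::TukeyHSD(fit)$labels)
  tk$pair <- rownames(tk); rownames(tk) <- NULL
  names(tk) <- c("diff", "lo", "hi", "p_adj", "pair")
  structure(list(summary = smry,
                 anova_F = at[["F value"]][1], anova_p = at[["Pr(>F)"]][1],
                 tukey = tk[, c("pair", "diff", "lo", "hi", "p_adj")]),
            class = "la_group_comparison")
}

#' Partial F-test between nested linear models
#'
#' Extra-sum-of-squares F-test of whether terms added to a linear
#' regression (a binary shift, its interaction with the slope, or a second
#' continuous predictor in a bilinear model) explain a significant amount
#' of residual variation.
#'
#' @param base,full Nested `lm` fits on the same observations.
#' @return List with `F`, `p`, `df1`, `df2`, `sse_base`, `sse_full`.
#' @export
partial_f_test <- function(base, full) {
  stopifnot(inherits(base, "lm"), inherits(full, "lm"))
  if (stats::nobs(base) != stats::nobs(full))
    stop("models were fitted to different numbers of observations",
         call. = FALSE)
  if (anyNA(stats::coef(full)))
    stop("full model is rank deficient (duplicated or collinear predictor)",
         call. = FALSE)
  tb <- attr(stats::terms(base), "term.labels")
  tf <- attr(stats::terms(full), "term.labels")
  if (!all(tb %in% tf) || length(tf) <= length(tb))
    stop("models are not nested", call. = FALSE)
  sse_b <- sum(stats::resid(base)^2)
  sse_f <- sum(stats::resid(full)^2)
  df1 <- base$df.residual - full$df.residual
  df2 <- full$df.residual
  Fstat <- ((sse_b - sse_f) / df1) / (sse_f / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, sse_base = sse_b, sse_full = sse_f)
}

#' Williams-Hotelling test for two dependent correlations
#'
#' Tests whether `cor(x, y)` and `cor(x, z)` differ, for correlations
#' sharing the variable `x`, using Williams' t statistic in the
#' determinant-of-correlation-matrix form on `n - 3` degrees of freedom.
#' Used to compare how strongly PAWP correlates with acceleration factors
#' from different measurement locations.
#'
#' Positively collinear `y` and `z` make the two correlations identical,
#' giving `t = 0`, `p = 1`; perfect anti-correlation is degenerate and is
#' an error.
#'
#' @param x,y,z Numeric vectors; incomplete triples are dropped.
#' @return An `la_cor_comparison` list: `r_xy`, `r_xz`, `r_yz`, `n`,
#'   `t_statistic`, `df`, `p_value` (two-sided).
#' @export
compare_dependent_correlations <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete triples", call. = FALSE)
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  if (r_yz >= 1 - 1e-12) {
    # y and z are positively collinear, so r_xy = r_xz identically:
    # the correlations cannot differ
    return(structure(list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz, n = n,
                          t_statistic = 0, df = n - 3, p_value = 1),
                     class = "la_cor_comparison"))
  }
  if (r_yz <= -1 + 1e-12)
    stop("y and z are perfectly anti-correlated; the test is degenerate",
         call. = FALSE)
  detR <- 1 - r_xy^2 - r_xz^2 - r_yz^2 + 2 * r_xy * r_xz * r_yz
  rbar <- (r_xy + r_xz) / 2
  tstat <- (r_xy - r_xz) *
    sqrt((n - 1) * (1 + r_yz) /
           (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_yz)^3))
  p <- 2 * stats::pt(-abs(tstat), n - 3)
  structure(list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz, n = n,
                 t_statistic = tstat, df = n - 3, p_value = p),
            class = "la_cor_comparison")
}

#' One-sample t-test against zero
#'
#' Two-sided test of whether paired differences (e.g. between velocities
#' measured at two locations) have zero mean. With zero variance the
#' statistic is degenerate: all-zero differences give `t = 0`, `p = 1`;
#' constant non-zero differences give `t = +/-Inf`, `p = 0`.
#'
#' @param d Differences; `NA`s dropped.
#' @return List with `mean`, `sd`, `n`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 finite differences", call. = FALSE)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  list(mean = m, sd = s, n = n, t = t, df = n - 1, p = p)
}
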
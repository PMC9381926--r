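#' Group specification for the synthetic PH cohort
#'
#' Describes one diagnostic group of the simulated right-heart-catheter
#' cohort: its size, the truncated-normal distribution of mean pulmonary
#' artery wedge pressure (PAWP), and the group-conditional means and SDs of
#' the pulmonary venous inflow peaks (`v_S`, `v_D`) and the late diastolic
#' transmitral peak (`v_A`).
#'
#' @param name Group label, one of `"non_PH"`, `"pre_capillary_PH"`,
#'   `"post_capillary_PH"`.
#' @param n Number of patients in the group.
#' @param pawp_mean,pawp_sd Mean and SD of the untruncated PAWP normal, mmHg.
#' @param pawp_lo,pawp_hi Truncation bounds for PAWP, mmHg
#'   (`pawp_lo < pawp_hi`). Post-capillary PH is defined by PAWP > 15 mmHg,
#'   so its lower bound sits at 15 to keep group label and pressure
#'   concordant.
#' @param vS_mean,vS_sd,vD_mean,vD_sd,vA_mean,vA_sd Group-conditional moments
#'   of the velocity peaks, cm/s.
#' @return A `la_group_spec` list.
#' @export
group_spec <- function(name, n, pawp_mean, pawp_sd, pawp_lo, pawp_hi,
                       vS_mean, vS_sd, vD_mean, vD_sd, vA_mean, vA_sd) {
  name <- match.arg(name, c("non_PH", "pre_capillary_PH", "post_capillary_PH"))
  stopifnot(n > 0, pawp_sd > 0, pawp_lo < pawp_hi,
            vS_sd > 0, vD_sd > 0, vA_sd > 0)
  structure(list(name = name, n = as.integer(n),
                 pawp_mean = pawp_mean, pawp_sd = pawp_sd,
                 pawp_lo = pawp_lo, pawp_hi = pawp_hi,
                 vS_mean = vS_mean, vS_sd = vS_sd,
                 vD_mean = vD_mean, vD_sd = vD_sd,
                 vA_mean = vA_mean, vA_sd = vA_sd),
            class = "la_group_spec")
}

#' Default three-group cohort structure
#'
#' 28 non-PH, 21 pre-capillary PH and 13 post-capillary PH patients with
#' group PAWP distributions 8 +/- 4, 10 +/- 4 and 18 +/- 3 mmHg. Non-PH and
#' pre-capillary PAWP are truncated to (0, 15], post-capillary to (15, 28],
#' so the post-capillary label coincides exactly with PAWP > 15 mmHg.
#' Velocity moments are the group columns of the published velocity table
#' (v_S 39/32/24, v_D 33/33/31, v_A 38/39/42 cm/s), which encode the
#' negative v_S-PAWP dependence without an explicit regression.
#'
#' @return List of three [group_spec()] objects.
#' @export
default_groups <- function() {
  list(
    group_spec("non_PH", 28, 8, 4, 0, 15, 39, 11, 33, 9, 38, 10),
    group_spec("pre_capillary_PH", 21, 10, 4, 0, 15, 32, 10, 33, 9, 39, 16),
    group_spec("post_capillary_PH", 13, 18, 3, 15, 28, 24, 14, 31, 9, 42, 27)
  )
}

# Pooled ("All"-column) velocity moments and the marginal moments /
# junction correlations of the alternative measurement locations.
# Used to standardise junction draws and to induce the printed
# alt-location correlation structure; the printed biases (e.g. the
# +6 cm/s v_E,tip offset with SD 9) follow from these moments.
.pooled_moments <- function() {
  list(vS = c(mean = 34, sd = 13), vD = c(mean = 33, sd = 9),
       vE = c(mean = 54, sd = 19), vA = c(mean = 39, sd = 16))
}
.alt_moments <- function() {
  list(vS_vein = c(mean = 35, sd = 11, r = 0.73),
       vD_vein = c(mean = 34, sd = 10, r = 0.44),
       vE_tip  = c(mean = 60, sd = 19, r = 0.88),
       vA_tip  = c(mean = 40, sd = 17, r = 0.81))
}

#' Configuration of the synthetic cohort generator
#'
#' The generator plants a linear law between the LA acceleration factor
#' `alpha` and PAWP, `alpha = intercept + slope * PAWP + eps`, with noise on
#' the alpha scale, and derives the transmitral outflow peak from it:
#' `v_E = alpha * (v_S + v_D) / 2`. Defaults reproduce the published
#' calibration `alpha = 0.61 + 0.10 * PAWP` with residual scatter of
#' 2.0 mmHg on the pressure scale (noise SD 0.20 x inverse slope 10).
#'
#' @param groups List of [group_spec()] objects; defaults to
#'   [default_groups()].
#' @param alpha_intercept,alpha_slope Intercept (dimensionless) and slope
#'   (per mmHg) of the planted alpha-PAWP law.
#' @param alpha_noise_sd SD of the alpha-scale residual noise.
#' @param monophasic_fraction Probability that a patient has a monophasic
#'   transmitral profile (no distinct late diastolic A peak), in which case
#'   `v_A` is missing. Default 6/62.
#' @param rho_vS_vD Correlation between the two pulmonary venous inflow
#'   peaks within a group (default 0.38).
#' @param rho_vS_vA Target correlation between `v_S` and `v_A`, induced
#'   through a latent factor shared with `v_S` (default 0.58).
#' @param p_left_vein Probability that the left inferior pulmonary vein
#'   carries the higher velocities and is selected (default 25/62). The
#'   label carries no distributional consequence for the junction peaks.
#' @param max_retries Maximum rejection-sampling passes used to keep all
#'   velocities strictly positive.
#' @param seed Integer seed; when non-`NULL`, [generate_cohort()] is fully
#'   deterministic.
#' @return A `la_cohort_config` list.
#' @export
cohort_config <- function(groups = default_groups(),
                          alpha_intercept = 0.61,
                          alpha_slope = 0.10,
                          alpha_noise_sd = 0.20,
                          monophasic_fraction = 6 / 62,
                          rho_vS_vD = 0.38,
                          rho_vS_vA = 0.58,
                          p_left_vein = 25 / 62,
                          max_retries = 1000L,
                          seed = NULL) {
  stopifnot(length(groups) >= 1, alpha_slope > 0, alpha_noise_sd >= 0,
            monophasic_fraction >= 0, monophasic_fraction < 1,
            abs(rho_vS_vD) < 1, abs(rho_vS_vA) < 1,
            p_left_vein >= 0, p_left_vein <= 1, max_retries >= 1)
  for (g in groups) stopifnot(inherits(g, "la_group_spec"))
  structure(list(groups = groups, alpha_intercept = alpha_intercept,
                 alpha_slope = alpha_slope, alpha_noise_sd = alpha_noise_sd,
                 monophasic_fraction = monophasic_fraction,
                 rho_vS_vD = rho_vS_vD, rho_vS_vA = rho_vS_vA,
                 p_left_vein = p_left_vein,
                 max_retries = as.integer(max_retries), seed = seed),
            class = "la_cohort_config")
}

# inverse-CDF draw from a truncated normal (exact, no rejection needed)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# redraw entries failing `ok` until all pass or max_retries passes are
# spent; `draw(idx)` redraws the entries at positions idx
.redraw_until <- function(x, draw, ok, max_retries, what) {
  for (i in seq_len(max_retries)) {
    bad <- which(!ok(x))
    if (!length(bad)) return(x)
    x[bad] <- draw(bad)
  }
  if (any(!ok(x)))
    stop("could not draw strictly positive ", what, " after ",
         max_retries, " retries; check the configured moments", call. = FALSE)
  x
}

#' Generate one synthetic cohort
#'
#' Draws a per-patient table of PAWP, the four LA peak velocities at the
#' atrial/atrio-ventricular junctions, and the alternative valve-tip and
#' intra-vein velocities. For each patient: PAWP comes from the group's
#' truncated normal; `(v_S, v_D)` from a group-conditional bivariate normal
#' with correlation `rho_vS_vD`, rejected to positive values; `v_A` shares a
#' latent factor with `v_S` (target correlation `rho_vS_vA`) and is set
#' missing for the monophasic subset; the true acceleration factor is
#' `alpha_intercept + alpha_slope * PAWP` plus alpha-scale noise, and
#' `v_E = alpha * (v_S + v_D) / 2`. Alternative-location velocities are
#' drawn conditionally on their junction counterpart with the published
#' marginal moments and correlations, so the valve-tip outflow peak carries
#' its positive bias (about +6 cm/s) by construction.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `la_cohort` with columns `patient_id`,
#'   `group`, `pawp_mmHg`, `vS`, `vD`, `vE`, `vA` (NA when monophasic),
#'   `vein_used`, `vS_vein`, `vD_vein`, `vE_tip`, `vA_tip` (NA when `vA`
#'   is).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' table(cohort$group)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "la_cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- lapply(config$groups, function(g) {
    n <- g$n
    pawp <- .rtruncnorm(n, g$pawp_mean, g$pawp_sd, g$pawp_lo, g$pawp_hi)

    rho <- config$rho_vS_vD
    draw_pair <- function(m) {
      z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
      cbind(vS = g$vS_mean + g$vS_sd * z1,
            vD = g$vD_mean + g$vD_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
    }
    sv <- draw_pair(n)
    for (i in seq_len(config$max_retries)) {
      bad <- sv[, 1] <= 0 | sv[, 2] <= 0
      if (!any(bad)) break
      sv[bad, ] <- draw_pair(sum(bad))
    }
    if (any(sv <= 0))
      stop("could not draw positive (v_S, v_D) pairs after ",
           config$max_retries, " retries", call. = FALSE)
    vS <- sv[, "vS"]; vD <- sv[, "vD"]

    zS <- (vS - g$vS_mean) / g$vS_sd
    rA <- config$rho_vS_vA
    draw_vA <- function(idx) {
      g$vA_mean + g$vA_sd * (rA * zS[idx] + sqrt(1 - rA^2) * stats::rnorm(length(idx)))
    }
    vA <- .redraw_until(draw_vA(seq_len(n)), draw_vA,
                        function(x) x > 0, config$max_retries, "v_A")

    draw_alpha <- function(idx) {
      config$alpha_intercept + config$alpha_slope * pawp[idx] +
        stats::rnorm(length(idx), 0, config$alpha_noise_sd)
    }
    alpha_true <- .redraw_until(draw_alpha(seq_len(n)), draw_alpha,
                                function(x) x > 0, config$max_retries,
                                "acceleration factor")
    vE <- alpha_true * (vS + vD) / 2

    mono <- stats::runif(n) < config$monophasic_fraction
    vA[mono] <- NA_real_

    data.frame(group = g$name, pawp_mmHg = pawp, vS = vS, vD = vD,
               vE = vE, vA = vA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_all <- nrow(out)
  out$patient_id <- sprintf("P%03d", seq_len(n_all))
  out$vein_used <- ifelse(stats::runif(n_all) < config$p_left_vein,
                          "left_inferior", "right_inferior")

  alt <- .alt_moments()
  for (nm in names(alt)) {
    a <- alt[[nm]]
    ref <- .pooled_moments()[[c(vS_vein = "vS", vD_vein = "vD",
                                vE_tip = "vE", vA_tip = "vA")[[nm]]]]
    zr <- (out[[sub("_(vein|tip)$", "", nm)]] - ref["mean"]) / ref["sd"]
    draw_alt <- function(idx) {
      a["mean"] + a["sd"] * (a["r"] * zr[idx] +
                               sqrt(1 - a["r"]^2) * stats::rnorm(length(idx)))
    }
    # NA propagates from a monophasic v_A; only finite draws must be positive
    out[[nm]] <- .redraw_until(draw_alt(seq_len(n_all)), draw_alt,
                               function(x) is.na(x) | x > 0,
                               config$max_retries, nm)
  }

  out <- out[, c("patient_id", "group", "pawp_mmHg", "vS", "vD", "vE", "vA",
                 "vein_used", "vS_vein", "vD_vein", "vE_tip", "vA_tip")]
  rownames(out) <- NULL
  class(out) <- c("la_cohort", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' One row per patient; missing `v_A` (monophasic transmitral profile) is an
#' empty field. UTF-8, '.' decimal separator. Writing then reading a cohort
#' is lossless up to numeric printing precision.
#'
#' @param cohort An `la_cohort` data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns an `la_cohort` data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "data.frame"))
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  needed <- c("patient_id", "group", "pawp_mmHg", "vS", "vD", "vE")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols))
    stop("cohort CSV lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  class(out) <- c("la_cohort", "data.frame")
  out
}
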
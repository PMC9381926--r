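#' Pipeline run configuration
#'
#' @param seed Integer seed; mandatory so every run is reproducible.
#' @param cohort A [cohort_config()] (its own seed, if any, is overridden
#'   by `seed`).
#' @param pawp_threshold PAWP positivity threshold, mmHg (default 15, the
#'   pre-/post-capillary boundary).
#' @param fixed_cutoff Acceleration-factor cut-off evaluated alongside the
#'   per-run regression-derived one (default 2.10, the published value).
#' @param out_dir Optional directory for `report.json`, `cohort.csv` and
#'   `roc_points.csv`.
#' @param waveform_roundtrip If `TRUE`, velocities are re-extracted from
#'   generated waveforms (zero-noise round trip) instead of taken from the
#'   cohort table, exercising the extraction path end to end.
#' @return An `la_run_config` list.
#' @export
run_config <- function(seed, cohort = cohort_config(),
                       pawp_threshold = 15, fixed_cutoff = 2.10,
                       out_dir = NULL, waveform_roundtrip = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 pawp_threshold = pawp_threshold,
                 fixed_cutoff = fixed_cutoff, out_dir = out_dir,
                 waveform_roundtrip = isTRUE(waveform_roundtrip)),
            class = "la_run_config")
}

# re-derive the four junction velocities of every record from zero-noise
# waveforms via peak detection (module-pair contract: exact round trip)
.roundtrip_velocities <- function(cohort, wconfig = waveform_config()) {
  for (i in seq_len(nrow(cohort))) {
    cv <- generate_waveforms(cohort[i, ], wconfig)
    out_p <- detect_outflow_peaks(cv$transmitral)
    in_p <- detect_inflow_peaks(cv$venous)
    cohort$vE[i] <- out_p$v_E
    cohort$vA[i] <- out_p$v_A
    cohort$vS[i] <- in_p$v_S
    cohort$vD[i] <- in_p$v_D
  }
  cohort
}

#' Run the full analysis pipeline on one synthetic cohort
#'
#' Generates a cohort, computes the acceleration factor and its
#' location variants, and reproduces the complete statistical evaluation:
#' group comparison of alpha (ANOVA + Tukey-Kramer), the free and
#' fixed-`c_out` general-ratio fits, the linear calibration with PRESS,
#' the inverted-regression Bland-Altman agreement, ROC analyses for
#' PAWP > threshold in all patients and for post-capillary PH among PH
#' patients, one-sample t-tests of the location biases, and
#' Williams-Hotelling comparisons of the location-variant correlations
#' with PAWP. Fully reproducible under `config$seed`.
#'
#' @param config An [run_config()].
#' @return An `la_report` list; written as JSON/CSV when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "la_run_config"))
  cc <- config$cohort
  cc$seed <- config$seed
  cohort <- generate_cohort(cc)
  if (config$waveform_roundtrip) cohort <- .roundtrip_velocities(cohort)
  cohort <- alpha_variants(cohort, quiet = TRUE)

  groups <- compare_groups(cohort$alpha, cohort$group)
  ratio_free <- fit_general_ratio(cohort)
  ratio_fixed <- fit_general_ratio(cohort, fix_c_out = 1)
  cal <- fit_calibration(cohort$alpha, cohort$pawp_mmHg)
  pawp_calc <- predict_pawp(cal, cohort$alpha)
  ba <- bland_altman(cohort$pawp_mmHg, pawp_calc)

  pos <- cohort$pawp_mmHg > config$pawp_threshold
  roc_all <- roc_analysis(cohort$alpha, pos, calibration = cal,
                          threshold_pawp = config$pawp_threshold)
  fixed_rule <- .sens_spec_at(cohort$alpha, pos, config$fixed_cutoff)

  ph <- cohort$group %in% c("pre_capillary_PH", "post_capillary_PH")
  roc_ph <- roc_analysis(cohort$alpha[ph],
                         cohort$group[ph] == "post_capillary_PH",
                         calibration = cal,
                         threshold_pawp = config$pawp_threshold)

  location_bias <- list(
    vE_tip = one_sample_t(cohort$vE_tip - cohort$vE),
    vA_tip = one_sample_t(cohort$vA_tip - cohort$vA),
    vS_vein = one_sample_t(cohort$vS_vein - cohort$vS),
    vD_vein = one_sample_t(cohort$vD_vein - cohort$vD),
    alpha_tip = one_sample_t(cohort$alpha_tip - cohort$alpha),
    alpha_vein = one_sample_t(cohort$alpha_vein - cohort$alpha),
    alpha_tip_vein = one_sample_t(cohort$alpha_tip_vein - cohort$alpha))
  location_corr <- list(
    alpha_tip = compare_dependent_correlations(
      cohort$pawp_mmHg, cohort$alpha, cohort$alpha_tip),
    alpha_vein = compare_dependent_correlations(
      cohort$pawp_mmHg, cohort$alpha, cohort$alpha_vein),
    alpha_tip_vein = compare_dependent_correlations(
      cohort$pawp_mmHg, cohort$alpha, cohort$alpha_tip_vein))

  report <- structure(list(
    seed = config$seed,
    n = nrow(cohort),
    cohort = cohort,
    groups = groups,
    general_ratio = ratio_free,
    general_ratio_fixed_c_out = ratio_fixed,
    calibration = cal,
    bland_altman = ba,
    roc_pawp = roc_all,
    fixed_cutoff_rule = fixed_rule,
    roc_postcapillary_in_ph = roc_ph,
    location_bias = location_bias,
    location_correlations = location_corr),
    class = "la_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
    utils::write.csv(roc_all$points,
                     file.path(config$out_dir, "roc_points.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Flatten a pipeline report for JSON serialisation
#'
#' Drops model objects and the per-patient table, keeping every statistic.
#'
#' @param report An `la_report`.
#' @return A plain nested list.
#' @export
report_to_list <- function(report) {
  cal <- report$calibration
  gr <- report$general_ratio
  grf <- report$general_ratio_fixed_c_out
  strip <- function(x) x[setdiff(names(x), c("fit", "model"))]
  list(seed = report$seed, n = report$n,
       groups = list(summary = report$groups$summary,
                     anova_F = report$groups$anova_F,
                     anova_p = report$groups$anova_p,
                     tukey = report$groups$tukey),
       general_ratio = strip(unclass(gr)),
       general_ratio_fixed_c_out = strip(unclass(grf)),
       calibration = strip(unclass(cal)),
       bland_altman = unclass(report$bland_altman),
       roc_pawp = unclass(report$roc_pawp),
       fixed_cutoff_rule = report$fixed_cutoff_rule,
       roc_postcapillary_in_ph = unclass(report$roc_postcapillary_in_ph),
       location_bias = report$location_bias,
       location_correlations = lapply(report$location_correlations, unclass))
}

#' Headline statistics of one cohort
#'
#' The per-cohort quantities summarised across replicates: Pearson r of
#' alpha with PAWP, the calibration slope/intercept, the SD of differences
#' between PAWP and back-calculated PAWP, the regression-derived cut-off
#' at the PAWP threshold, the AUC (and sensitivity/specificity of the
#' fixed published rule alpha > 2.10) for PAWP > 15 mmHg, cohort and
#' post-capillary-group mean alpha, and the AUC for post-capillary PH
#' among PH patients.
#'
#' @param cohort An `la_cohort` (alpha column added if absent).
#' @param fixed_cutoff Fixed classification cut-off (default 2.10).
#' @param pawp_threshold PAWP positivity threshold, mmHg.
#' @return Named numeric vector.
#' @export
cohort_stats <- function(cohort, fixed_cutoff = 2.10, pawp_threshold = 15) {
  if (!"alpha" %in% names(cohort))
    cohort$alpha <- la_alpha(cohort$vE, cohort$vS, cohort$vD)
  a <- cohort$alpha; p <- cohort$pawp_mmHg
  cal <- fit_calibration(a, p)
  ba <- bland_altman(p, predict_pawp(cal, a))
  pos <- p > pawp_threshold
  auc <- .auc_midrank(a, pos)
  sens <- mean(a[pos] > fixed_cutoff)
  spec <- mean(a[!pos] <= fixed_cutoff)
  ph <- cohort$group %in% c("pre_capillary_PH", "post_capillary_PH")
  auc_ph <- .auc_midrank(a[ph], cohort$group[ph] == "post_capillary_PH")
  c(r = cal$r, slope = cal$slope_b, intercept = cal$intercept_a,
    sd_diff = ba$sd_diff,
    cutoff_regression = cal$intercept_a + cal$slope_b * pawp_threshold,
    auc = auc, sensitivity_pct = 100 * sens, specificity_pct = 100 * spec,
    mean_alpha = mean(a), mean_alpha_postcapillary =
      mean(a[cohort$group == "post_capillary_PH"]),
    auc_postcapillary_in_ph = auc_ph)
}

#' Replicate the cohort simulation and summarise headline statistics
#'
#' Draws `n_replicates` independent cohorts from `config` (per-replicate
#' seeds derived deterministically from `seed`) and returns the
#' per-replicate [cohort_stats()] together with their means.
#'
#' @param n_replicates Number of cohorts.
#' @param seed Master seed.
#' @param config A [cohort_config()].
#' @param fixed_cutoff,pawp_threshold Passed to [cohort_stats()].
#' @return List with `stats` (one row per replicate) and `means`.
#' @export
replicate_summary <- function(n_replicates = 500, seed = 1,
                              config = cohort_config(),
                              fixed_cutoff = 2.10, pawp_threshold = 15) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- vapply(seeds, function(s) {
    config$seed <- s
    cohort_stats(generate_cohort(config), fixed_cutoff, pawp_threshold)
  }, numeric(11))
  stats_df <- as.data.frame(t(rows))
  list(stats = stats_df, means = colMeans(stats_df),
       n_replicates = n_replicates, seed = seed)
}
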
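#!/usr/bin/env Rscript
# Calibration and diagnostic evaluation: linear law alpha = a + b * PAWP
# with PRESS cross-validation, inversion to PAWP_calc with Bland-Altman
# agreement, and ROC analysis of alpha for PAWP > 15 mmHg (all patients)
# and for post-capillary PH among PH patients.
library(laflow)

cohort <- alpha_variants(read_cohort_csv("results/cohort.csv"), quiet = TRUE)

grp <- compare_groups(cohort$alpha, cohort$group)
cat("Mean alpha by group:\n")
print(within(grp$summary, { mean <- round(mean, 2); sd <- round(sd, 2) }))
cat("ANOVA p =", format.pval(grp$anova_p), "\n\n")

cal <- fit_calibration(cohort$alpha, cohort$pawp_mmHg)
cat(sprintf("alpha = %.2f + %.3f * PAWP   (r = %.2f, r^2 - PRESS R^2 = %.3f)\n",
            cal$intercept_a, cal$slope_b, cal$r, cal$r^2 - cal$press_r2))
cat(sprintf("PAWP_calc = %.1f + %.1f * alpha\n",
            cal$inverse_intercept, cal$inverse_slope))

ba <- bland_altman(cohort$pawp_mmHg, predict_pawp(cal, cohort$alpha))
cat(sprintf("Bland-Altman: bias %.2f mmHg, SD of differences %.2f mmHg, LoA %.1f to %.1f\n\n",
            ba$bias, ba$sd_diff, ba$loa_low, ba$loa_high))

roc <- roc_analysis(cohort$alpha, cohort$pawp_mmHg > 15, calibration = cal)
cat(sprintf("ROC for PAWP > 15 mmHg: AUC %.2f (95%% CI %.2f-%.2f)\n",
            roc$auc, roc$ci95_auc[1], roc$ci95_auc[2]))
cat(sprintf("  regression cut-off alpha = %.2f: sens %.0f%%, spec %.0f%%\n",
            roc$regression$cutoff, 100 * roc$regression$sensitivity,
            100 * roc$regression$specificity))
cat(sprintf("  Youden cut-off alpha = %.2f: sens %.0f%%, spec %.0f%%\n",
            roc$youden$cutoff, 100 * roc$youden$sensitivity,
            100 * roc$youden$specificity))

ph <- cohort$group %in% c("pre_capillary_PH", "post_capillary_PH")
roc_ph <- roc_analysis(cohort$alpha[ph],
                       cohort$group[ph] == "post_capillary_PH",
                       calibration = cal)
cat(sprintf("ROC for post-capillary PH among PH: AUC %.2f (95%% CI %.2f-%.2f), Youden cut-off %.2f\n",
            roc_ph$auc, roc_ph$ci95_auc[1], roc_ph$ci95_auc[2],
            roc_ph$youden$cutoff))

utils::write.csv(roc$points, "results/roc_points.csv", row.names = FALSE)
jsonlite::write_json(
  list(groups = list(summary = grp$summary, anova_p = grp$anova_p,
                     tukey = grp$tukey),
       calibration = unclass(cal)[setdiff(names(cal), "model")],
       bland_altman = unclass(ba),
       roc_pawp = unclass(roc), roc_postcapillary_in_ph = unclass(roc_ph)),
  "results/diagnostics.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/roc_points.csv, results/diagnostics.json\n")
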
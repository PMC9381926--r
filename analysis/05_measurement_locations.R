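#!/usr/bin/env Rscript
# Impact of the velocity-measurement location: biases of the valve-tip and
# intra-vein peaks against the junction peaks (one-sample t-tests) and
# Williams-Hotelling comparison of how strongly each location's
# acceleration factor correlates with PAWP.
library(laflow)

cohort <- alpha_variants(read_cohort_csv("results/cohort.csv"), quiet = TRUE)

cat("Location biases (alternative - junction):\n")
pairs <- list(vE_tip = c("vE_tip", "vE"), vA_tip = c("vA_tip", "vA"),
              vS_vein = c("vS_vein", "vS"), vD_vein = c("vD_vein", "vD"),
              alpha_tip = c("alpha_tip", "alpha"),
              alpha_vein = c("alpha_vein", "alpha"),
              alpha_tip_vein = c("alpha_tip_vein", "alpha"))
bias <- lapply(names(pairs), function(nm) {
  d <- cohort[[pairs[[nm]][1]]] - cohort[[pairs[[nm]][2]]]
  res <- one_sample_t(d)
  cat(sprintf("  %-14s %6.2f +/- %5.2f   p = %s\n", nm, res$mean, res$sd,
              format.pval(res$p, digits = 3)))
  res
})
names(bias) <- names(pairs)

cat("\nCorrelation with PAWP (Williams-Hotelling vs junction alpha):\n")
wh <- lapply(c("alpha_tip", "alpha_vein", "alpha_tip_vein"), function(v) {
  res <- compare_dependent_correlations(cohort$pawp_mmHg, cohort$alpha,
                                        cohort[[v]])
  cat(sprintf("  r(PAWP, alpha) = %.2f vs r(PAWP, %s) = %.2f:  t = %.2f, p = %s\n",
              res$r_xy, v, res$r_xz, res$t_statistic,
              format.pval(res$p_value, digits = 3)))
  res
})
names(wh) <- c("alpha_tip", "alpha_vein", "alpha_tip_vein")

jsonlite::write_json(list(bias = bias, williams = lapply(wh, unclass)),
                     "results/locations.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/locations.json\n")
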
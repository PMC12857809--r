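#!/usr/bin/env Rscript
# Calibration of the OR* permutation null: on a well-mixed ROI the observed
# OR* should be unexceptional under random relabeling, and on a segregated
# ROI it should sit at the bottom of the null. Writes
# results/permutation_null.tsv.

library(epimm)

seed <- 2026L

mixed <- simulate_spatial_roi(100, 100, mixing = 1, seed = seed, roi_id = "mixed")
seg <- simulate_spatial_roi(100, 100, mixing = 0, seed = seed, roi_id = "segregated")

summarize <- function(ct) {
  g <- build_proximity_graph(ct)
  nd <- permutation_null(g, "EPI", "IMM", n_perm = 2000, seed = seed)
  data.frame(roi_id = nd$roi_id, observed_or_star = nd$observed_or_star,
             null_mean_log = mean(log(nd$or_star_samples)),
             null_sd_log = sd(log(nd$or_star_samples)),
             empirical_p = nd$empirical_p, n_perm = nd$n_perm)
}
tab <- rbind(summarize(mixed), summarize(seg))

dir.create("results", showWarnings = FALSE)
epimm:::write_tsv_provenance(tab, "results/permutation_null.tsv",
                             "OR* permutation null calibration",
                             list(seed = seed, n_perm = 2000))
print(tab, digits = 4)
cat(sprintf("\nWell-mixed ROI: empirical p = %.3f (unexceptional, as it should be).\n",
            tab$empirical_p[1]))
cat(sprintf("Segregated ROI: observed OR* = %.2g ranks below every permutation (p = %.3f).\n",
            tab$observed_or_star[2], tab$empirical_p[2]))
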
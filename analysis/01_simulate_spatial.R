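#!/usr/bin/env Rscript
# Simulate two-type ROIs across the mixing grid and quantify how the
# geometric interaction odds ratio OR* responds to spatial intermingling.
# Writes results/spatial_or_star.tsv (one row per simulated ROI).

library(epimm)

seed <- 2026L
lambdas <- c(0, 0.25, 0.5, 0.75, 1)
n_rep <- 25L

rows <- list()
for (i in seq_along(lambdas)) {
  for (rep in seq_len(n_rep)) {
    roi_id <- sprintf("lam%02d_rep%02d", round(100 * lambdas[i]), rep)
    ct <- simulate_spatial_roi(100, 100, lambdas[i],
                               seed = seed + 1000L * i + rep, roi_id = roi_id)
    g <- build_proximity_graph(ct, max_edge_len = 50)
    odds <- compute_interaction_odds(classify_edges(g, "EPI", "IMM"))
    rows[[roi_id]] <- data.frame(
      roi_id = roi_id, lambda = lambdas[i], n_edges = nrow(g$edges),
      eAB = odds$eAB, eAA = odds$eAA, eBB = odds$eBB,
      or_star = odds$or_star, corrected = odds$corrected)
  }
}
tab <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
epimm:::write_tsv_provenance(tab, "results/spatial_or_star.tsv",
                             "simulated OR* across mixing grid",
                             list(seed = seed, n_rep = n_rep))

med <- tapply(tab$or_star, tab$lambda, median)
cat("Median OR* by mixing level:\n")
print(round(med, 4))
cat(sprintf("\nOR* rises monotonically with mixing (%s).\n",
            if (all(diff(med) > 0)) "strictly increasing" else "NOT monotone"))
cat("At lambda = 0 the Gaussian tails still allow occasional cross-type contact:\n")
cat(sum(tab$eAB[tab$lambda == 0] == 0), "of", n_rep,
    "replicates have eAB = 0 (these use the Haldane-Anscombe correction).\n")
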
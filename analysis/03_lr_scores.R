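#!/usr/bin/env Rscript
# Ligand-receptor weighted co-expression: simulate small dense ROIs across
# the mixing grid, couple ligand/receptor expression to spatial mixedness,
# and compute the per-ROI geometric-mean interaction score with the default
# four-pair recruitment panel. Writes results/lr_scores.tsv.

library(epimm)

seed <- 2026L
panel <- default_lr_panel()
lambdas <- rep(seq(0, 1, length.out = 10), each = 5)

cells <- do.call(rbind, lapply(seq_along(lambdas), function(i) {
  as.data.frame(simulate_spatial_roi(10, 10, lambdas[i], field_size = 120,
                                     cluster_sd = 8, seed = seed + i,
                                     roi_id = sprintf("roi%02d", i)))
}))
ct <- cell_table(cells)

expr <- simulate_roi_expression(ct, panel, coupling = 2, seed = seed)
odds <- lapply(unique(ct$roi_id), function(roi) {
  g <- build_proximity_graph(cell_table(ct[ct$roi_id == roi, ]))
  compute_interaction_odds(classify_edges(g, "EPI", "IMM"))
})
names(odds) <- unique(ct$roi_id)

res <- roi_interaction_score(expr$epi, expr$imm, panel, odds)
tab <- res$summary
tab$lambda <- lambdas[match(tab$roi_id, unique(ct$roi_id))]
tab$mixedness <- expr$mixedness[tab$roi_id]

dir.create("results", showWarnings = FALSE)
epimm:::write_tsv_provenance(tab, "results/lr_scores.tsv",
                             "geometric-mean L-R interaction scores",
                             list(seed = seed, coupling = 2, panel = "default"))

rho_lig <- cor(expr$epi$values["CCL26", ], expr$mixedness, method = "spearman")
rho_score <- cor(tab$score, tab$mixedness, method = "spearman")
cat(sprintf("Simulated ligand expression tracks mixedness (Spearman %.2f).\n", rho_lig))
cat(sprintf("Per-ROI interaction score vs mixedness: Spearman %.2f.\n", rho_score))
cat("Note the weighting divides co-expression by OR*, so the score is NOT a\n")
cat("monotone readout of mixing: well-mixed ROIs are down-weighted by design.\n")
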
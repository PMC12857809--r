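test_that("module score vanishes on constant matrices and is shift-invariant", {
  const <- expression_matrix(matrix(2.5, 30, 4,
                                    dimnames = list(sprintf("g%02d", 1:30),
                                                    sprintf("u%d", 1:4))),
                             norm_state = "arbitrary")
  sig <- gene_set("s", c("g01", "g05"))
  ms <- module_score(const, sig, n_bins = 5, n_ctrl = 10, seed = 1)
  expect_equal(ms$scores, rep(0, 4))

  em <- make_expr(30, 5, seed = 2)
  base <- module_score(em, sig, n_bins = 5, n_ctrl = 20, seed = 3)
  shifted <- expression_matrix(em$values + 7.3, norm_state = "arbitrary")
  ms2 <- module_score(shifted, sig, n_bins = 5, n_ctrl = 20, seed = 3)
  expect_equal(ms2$scores, base$scores, tolerance = 1e-12)
  # reproducible under a fixed seed, different under another
  expect_equal(module_score(em, sig, n_bins = 5, n_ctrl = 20, seed = 3)$scores,
               base$scores)
  expect_equal(base$params, list(n_bins = 5L, n_ctrl = 20L, seed = 3L))
})

test_that("module score matches the step-by-step oracle", {
  em <- make_expr(10, 5, seed = 7)
  sig <- gene_set("sig10", c("g01", "g04", "g09", "NOT_PRESENT"))
  got <- module_score(em, sig, n_bins = 4, n_ctrl = 15, seed = 11)
  expect_equal(got$scores, module_score_oracle(em, sig, 4, 15, 11),
               tolerance = 1e-12)
  expect_error(module_score(em, gene_set("none", "ABSENT"), n_bins = 4),
               "ABSENT")
  expect_error(module_score(em, sig, n_bins = 10), "more genes than bins")
})

test_that("rank-enrichment score matches hand enumeration and is rank-invariant", {
  em <- expression_matrix(matrix(c(10, 8, 6, 4, 2), 5, 1,
                                 dimnames = list(paste0("g", 1:5), "u1")),
                          norm_state = "arbitrary")
  top <- gene_set("top", "g1")
  # alpha = 0: walk gives 1, then 1 - 1/4, 1 - 2/4, 1 - 3/4, 1 - 4/4
  expect_equal(ssgsea_score(em, top, alpha = 0)$scores,
               1 + 0.75 + 0.5 + 0.25 + 0, tolerance = 1e-12)

  em2 <- make_expr(10, 4, seed = 5)
  sig <- gene_set("s", c("g02", "g07", "g10"))
  got <- ssgsea_score(em2, sig, alpha = 0.25)
  expect_equal(got$scores, ssgsea_oracle(em2, sig, 0.25), tolerance = 1e-12)

  # strictly monotone per-unit transform leaves scores unchanged
  mono <- expression_matrix(exp(em2$values / 2), norm_state = "arbitrary")
  expect_equal(ssgsea_score(mono, sig, alpha = 0.25)$scores, got$scores,
               tolerance = 1e-12)
  # magnitudes are irrelevant given identical rankings
  scaled <- expression_matrix(em2$values * 100, norm_state = "arbitrary")
  expect_equal(ssgsea_score(scaled, sig, alpha = 0)$scores,
               ssgsea_score(em2, sig, alpha = 0)$scores, tolerance = 1e-12)

  all_genes <- gene_set("all", em_genes(em2))
  expect_error(ssgsea_score(em2, all_genes), "complement is empty")
})

test_that("Wilcoxon marker test is exact on small groups and antisymmetric", {
  m <- rbind(gene1 = c(1, 2, 3, 4, 5, 6),
             flat = c(5, 5, 5, 5, 5, 5))
  em <- expression_matrix(m, c("gene1", "flat"),
                          c("a1", "a2", "a3", "b1", "b2", "b3"),
                          norm_state = "arbitrary")
  tab <- rank_de_test(em, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                      min_lfc = 0.25, min_pct = 0.25)
  # {1,2,3} vs {4,5,6}: the most extreme of the 20 rank assignments, both tails
  expect_equal(tab$p[tab$gene == "gene1"], 0.1, tolerance = 1e-12)
  expect_equal(tab$log_fc[tab$gene == "gene1"], mean(1:3) - mean(4:6))
  # identical values in both groups: log_fc = 0, removed by the pre-filter
  expect_false("flat" %in% tab$gene)

  sw <- rank_de_test(em, c("b1", "b2", "b3"), c("a1", "a2", "a3"))
  expect_equal(sw$log_fc[sw$gene == "gene1"],
               -tab$log_fc[tab$gene == "gene1"])
  expect_equal(sw$p, tab$p)

  expect_error(rank_de_test(em, character(0), c("b1", "b2")), "empty group")
  expect_error(rank_de_test(em, c("a1", "a2"), c("a2", "b1")), "disjoint")
})

test_that("pre-filters and correction scope follow the marker-selection rules", {
  # 5 genes, exactly 2 pass both |log_fc| > 0.25 and pct > 0.25
  m <- rbind(
    up_strong = c(3, 3.2, 3.1, 2.9, 3.0, 1, 1.2, 1.1, 0.9, 1.0),  # lfc 2, pct 1
    dn_strong = c(0, 0, 0, 1.1, 1.2, 2, 2.2, 2.4, 2.1, 2.3),      # lfc < -0.25
    small_fc = c(1, 1.1, 1.2, 1.0, 1.1, 1.05, 1.15, 1.1, 1.0, 1.05),
    rare = c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # lfc 0.4 but pct 0.2 in both
    zero = rep(0, 10))
  em <- expression_matrix(m, rownames(m),
                          c(paste0("a", 1:5), paste0("b", 1:5)),
                          norm_state = "arbitrary")
  tab <- rank_de_test(em, paste0("a", 1:5), paste0("b", 1:5),
                      min_lfc = 0.25, min_pct = 0.25, correction = "bonferroni")
  expect_setequal(tab$gene, c("up_strong", "dn_strong"))
  # bonferroni over tested genes only (2, not 5)
  expect_equal(tab$p_adj, pmin(tab$p * 2, 1))
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("cross-region Spearman matches the exact permutation distribution", {
  mk <- function(ids, v) structure(list(signature = "s", unit_ids = ids,
                                        scores = v, method = "module_score",
                                        params = list()),
                                   class = "signature_scores")
  up <- mk(paste0("r", 1:6), c(0.1, 0.4, 0.9, 1.3, 2.2, 3.1))
  dn <- mk(paste0("r", 1:6), -c(0.1, 0.4, 0.9, 1.3, 2.2, 3.1))
  expect_equal(region_score_correlation(up, up)$rho, 1)
  expect_equal(region_score_correlation(up, dn)$rho, -1)

  withr::with_seed(13, {
    a <- mk(paste0("r", 1:5), runif(5))
    b <- mk(paste0("r", 1:5), runif(5))
  })
  got <- region_score_correlation(a, b)
  want <- spearman_perm_oracle(a$scores, b$scores)
  expect_equal(want$n_perm, 120L)
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # explicit pairing: epithelial ROI mapped to a differently named immune ROI
  b2 <- mk(paste0("imm", 1:5), b$scores)
  pairing <- stats::setNames(paste0("imm", 1:5), paste0("r", 1:5))
  expect_equal(region_score_correlation(a, b2, pairing)$rho, got$rho)

  expect_error(region_score_correlation(mk(c("x", "y"), c(1, 2)),
                                        mk(c("x", "y"), c(2, 1))),
               "at least 3")
})
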
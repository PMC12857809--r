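# Pseudobulk profiles exactly linear in a latent axis t: gene g has value
# a_g + b_g * t. PCA of the standardized profiles then has a straight line as
# its image, so the continuum must order samples exactly by t.
linear_cohort <- function(t, n_genes = 12, seed = 31) {
  withr::with_seed(seed, {
    a <- runif(n_genes, 1, 3)
    b <- runif(n_genes, -2, 2)
    m <- outer(a, rep(1, length(t))) + outer(b, t)
    m <- m - min(m)  # keep values non-negative
    expression_matrix(m, sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%02d", seq_along(t)), norm_state = "arbitrary")
  })
}

test_that("continuum gene selection applies the cell-count and recurrence filters", {
  genes <- paste0("g", 1:6)
  mk <- function(p, lfc) data.frame(gene = genes, p = p, log2_fc = lfc)
  de <- list(
    s1 = mk(c(1e-6, 1e-6, 0.5, 1e-6, 0.9, 1e-6), c(2, 0.5, 2, 0.4, 0.1, -0.7)),
    s2 = mk(c(1e-6, 0.8, 1e-6, 1e-6, 0.9, 1e-6), c(1.5, 2, 2, 0.3, 0.1, 0.8)),
    s3 = mk(rep(0.9, 6), rep(3, 6)),           # nothing significant here
    s4 = mk(rep(1e-6, 6), rep(3, 6)))          # dropped by the cell filter
  counts <- c(s1 = 200L, s2 = 120L, s3 = 80L, s4 = 50L)

  sel <- select_continuum_genes(de, counts)
  # hand application: s4 dropped (exactly 50 cells is not "more than 50");
  # g1 passes in s1+s2; g6 passes in s1+s2; g2,g3 pass once; g4 |lfc| too
  # small; g5 p too large
  expect_equal(sel$genes, c("g1", "g6"))

  expect_error(select_continuum_genes(de, c(s1 = 200, s2 = 50, s3 = 50, s4 = 50)),
               "fewer than 2 samples")
  expect_error(select_continuum_genes(de, counts, min_abs_lfc = 99),
               "no gene passes")
})

test_that("a cohort linear in a latent axis is ordered exactly by it", {
  t_true <- c(0, 0.2, 0.45, 0.7, 0.85, 1)
  pb <- linear_cohort(t_true)
  model <- fit_continuum(pb)
  coord <- model$training_placements$coordinate
  expect_equal(abs(cor(coord, t_true, method = "spearman")), 1)
  # loadings orthonormal, arc lengths non-decreasing from 0
  expect_equal(crossprod(model$pc_loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(model$arc_lengths[1], 0)
  expect_true(all(diff(model$arc_lengths) >= 0))
  # sign convention: first sample id sits in the lower half
  anchor <- model$training_placements$normalized[
    model$training_sample_ids == sort(model$training_sample_ids)[1]]
  expect_lte(anchor, 0.5)
})

test_that("continuum coordinates are invariant to gene order and duplicate-safe", {
  t_true <- c(0, 0.25, 0.5, 0.75, 1)
  pb <- linear_cohort(t_true)
  model <- fit_continuum(pb)
  perm <- withr::with_seed(3, sample(nrow(pb$values)))
  pb_perm <- expression_matrix(pb$values[perm, ], norm_state = "arbitrary")
  model_perm <- fit_continuum(pb_perm)
  expect_equal(model_perm$training_placements$coordinate,
               model$training_placements$coordinate, tolerance = 1e-8)

  # duplicated sample profiles land on identical coordinates
  v <- pb$values
  v <- cbind(v, s_dup = v[, 3])
  dup_model <- fit_continuum(expression_matrix(v, norm_state = "arbitrary"))
  pl <- dup_model$training_placements
  expect_equal(pl$coordinate[pl$sample_id == "s_dup"],
               pl$coordinate[pl$sample_id == "s03"])

  expect_error(fit_continuum(linear_cohort(c(0, 0.5, 1))), "at least 4 samples")
})

test_that("placement is self-consistent and handles mean profiles and overlap", {
  t_true <- seq(0, 1, length.out = 8)
  pb <- linear_cohort(t_true, n_genes = 15)
  model <- fit_continuum(pb)
  replaced <- place_on_continuum(model, pb)
  grid_step <- max(diff(model$arc_lengths))
  expect_lte(max(abs(replaced$coordinate - model$training_placements$coordinate)),
             grid_step + 1e-9)
  expect_equal(replaced$normalized,
               replaced$coordinate / max(model$arc_lengths))

  # the global training mean standardizes to the PCA origin
  mean_prof <- expression_matrix(matrix(model$gene_means,
                                        dimnames = list(model$genes, "mean_p")),
                                 norm_state = "arbitrary")
  got <- place_on_continuum(model, mean_prof)
  d0 <- sqrt(rowSums(model$spline_points^2))
  expect_equal(got$coordinate, model$arc_lengths[which.min(d0)])
  expect_equal(got$residual_distance, min(d0), tolerance = 1e-9)

  # fewer than half of the model genes present is an error
  few <- expression_matrix(pb$values[1:5, , drop = FALSE], norm_state = "arbitrary")
  expect_error(place_on_continuum(model, few), "50%")
  # partial overlap above the threshold works, with imputation recorded
  part <- expression_matrix(pb$values[1:10, , drop = FALSE], norm_state = "arbitrary")
  pl <- place_on_continuum(model, part)
  expect_equal(attr(pl, "imputed_fraction"), 5 / 15)
})

test_that("external cohort profiles project onto the right part of the axis", {
  cohort <- simulate_continuum_cohort(n_samples = 12, cells_per_sample = 120,
                                      n_genes = 80, module_size = 12,
                                      effect_size = 1.5, seed = 19)
  res <- continuum_from_counts(cohort$counts, reference = "S01")
  # an independently simulated cohort from the same generative model, at new
  # latent positions, must land in the right order after projection
  external <- simulate_continuum_cohort(n_samples = 9, cells_per_sample = 120,
                                        n_genes = 80, module_size = 12,
                                        effect_size = 1.5, seed = 57)
  logn <- lapply(external$counts, function(m)
    normalize_log_cpm(expression_matrix(m)))
  pb <- vapply(names(logn), function(s) rowMeans(logn[[s]]$values),
               numeric(80))
  profiles <- expression_matrix(pb, rownames(pb), paste0("ext_", colnames(pb)),
                                norm_state = "arbitrary")
  placed <- place_on_continuum(res$model, profiles)
  rho <- cor(placed$normalized, external$true_t, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("continuum models round-trip through JSON", {
  pb <- linear_cohort(seq(0, 1, length.out = 6))
  model <- fit_continuum(pb)
  path <- withr::local_tempfile(fileext = ".json")
  write_continuum_model(model, path)
  back <- read_continuum_model(path)
  expect_equal(back$genes, model$genes)
  expect_equal(back$spline_points, model$spline_points, tolerance = 1e-12)
  expect_equal(place_on_continuum(back, pb)$coordinate,
               place_on_continuum(model, pb)$coordinate, tolerance = 1e-9)
})

test_that("fraction trends recover monotone and constant relationships", {
  pl <- data.frame(sample_id = paste0("s", 1:10),
                   coordinate = seq(0, 9), normalized = seq(0, 1, length.out = 10),
                   residual_distance = 0)
  fr <- data.frame(sample_id = paste0("s", 1:10),
                   rising = seq(0.1, 0.6, length.out = 10),
                   flat = rep(0.3, 10))
  tr <- fraction_trend(pl, fr)
  expect_equal(tr$stats$rho[tr$stats$population == "rising"], 1)
  expect_equal(tr$stats$rho[tr$stats$population == "flat"], 0)
  expect_equal(tr$stats$p[tr$stats$population == "flat"], 1)
  expect_equal(nrow(tr$curves), 100L)  # 2 populations x 50 grid points

  fr$bad <- seq(0.5, 1.4, length.out = 10)
  expect_error(fraction_trend(pl, fr), "outside \\[0, 1\\]")
})
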
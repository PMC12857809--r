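#' Select continuum genes from per-sample differential-expression tables
#'
#' Each disease sample's basal cells are compared against control basal
#' cells, giving one DE table per sample. Samples with too few basal cells
#' are dropped (strictly more than `min_cells` are required). Within each
#' surviving sample's table, p-values are Benjamini-Hochberg adjusted; a
#' gene is selected iff it satisfies `p_adj <= max_padj` and
#' `|log2_fc| >= min_abs_lfc` in at least `min_samples` surviving samples.
#'
#' @param de_tables named list of data.frames with columns `gene`, `p`
#'   (raw p-values) and `log2_fc` (log2 fold change vs control).
#' @param basal_cell_counts named integer vector (same names) of basal-cell
#'   counts per sample.
#' @param min_cells cell-count filter (default 50; strict `>`).
#' @param max_padj BH-adjusted p-value cutoff (default 0.05, inclusive).
#' @param min_abs_lfc `|log2FC|` cutoff (default 0.5, inclusive).
#' @param min_samples minimum number of samples a gene must pass in
#'   (default 2).
#' @return a [gene_set()] named `"continuum_de"` (genes sorted
#'   alphabetically for determinism).
#' @export
select_continuum_genes <- function(de_tables, basal_cell_counts, min_cells = 50L,
                                   max_padj = 0.05, min_abs_lfc = 0.5,
                                   min_samples = 2L) {
  stopifnot(is.list(de_tables), !is.null(names(de_tables)))
  missing <- setdiff(names(de_tables), names(basal_cell_counts))
  if (length(missing)) {
    stop("no basal cell count for sample(s): ", paste(missing, collapse = ", "))
  }
  keep <- names(de_tables)[basal_cell_counts[names(de_tables)] > min_cells]
  if (length(keep) < 2L) {
    stop("fewer than 2 samples have more than ", min_cells, " basal cells")
  }
  passing <- lapply(de_tables[keep], function(tab) {
    stopifnot(all(c("gene", "p", "log2_fc") %in% names(tab)))
    padj <- stats::p.adjust(tab$p, method = "BH")
    tab$gene[padj <= max_padj & abs(tab$log2_fc) >= min_abs_lfc]
  })
  tally <- table(unlist(passing))
  selected <- sort(names(tally)[tally >= min_samples])
  if (!length(selected)) {
    stop("no gene passes the continuum criteria in >= ", min_samples,
         " samples; consider relaxing max_padj or min_abs_lfc")
  }
  gene_set("continuum_de", selected)
}

#' Fit the basal transition continuum
#'
#' Standardizes the selected genes (z-score across samples), runs PCA on the
#' samples, fits a loess spline of PC2 on PC1 (degree 2, tricube weights,
#' given span) evaluated on a 200-point grid over the PC1 range, and
#' accumulates arc lengths along the resulting polyline. The arc-length
#' coordinate along the spline is the continuum. The orientation is pinned
#' by convention: the training sample with the lexicographically smallest id
#' maps to the lower half of the coordinate.
#'
#' @param pseudobulk an [expression_matrix()] of per-sample pseudobulk
#'   profiles over the selected genes (genes x samples; >= 4 samples).
#'   Zero-variance genes are dropped with a warning.
#' @param span loess span (default 0.75).
#' @param n_grid number of spline vertices (default 200).
#' @return object of class `"continuum_model"`: list with `genes`,
#'   `gene_means`, `gene_sds`, `pc_loadings` (genes x 2, orthonormal),
#'   `spline_points` (n_grid x 2), `arc_lengths`, `span`,
#'   `training_sample_ids`, `training_scores` (samples x 2 PC scores), and
#'   `training_placements` (see [place_on_continuum()]).
#' @export
fit_continuum <- function(pseudobulk, span = 0.75, n_grid = 200L) {
  stopifnot(inherits(pseudobulk, "expr_matrix"))
  X <- pseudobulk$values
  samples <- colnames(X)
  if (ncol(X) < 4L) stop("continuum fitting needs at least 4 samples, got ", ncol(X))
  mu <- rowMeans(X)
  sd_g <- apply(X, 1L, stats::sd)
  if (any(sd_g == 0)) {
    warning("dropping ", sum(sd_g == 0), " zero-variance gene(s)")
    X <- X[sd_g > 0, , drop = FALSE]
    mu <- mu[sd_g > 0]
    sd_g <- sd_g[sd_g > 0]
  }
  if (nrow(X) < 2L) stop("fewer than 2 informative genes after standardization")
  Z <- (X - mu) / sd_g
  pca <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  if (ncol(pca$rotation) < 2L) stop("fewer than 2 principal components available")
  loadings <- pca$rotation[, 1:2, drop = FALSE]
  scores <- pca$x[, 1:2, drop = FALSE]
  if (stats::sd(scores[, 1L]) == 0) stop("PC1 is constant; no ordering possible")

  fit_df <- data.frame(pc1 = scores[, 1L], pc2 = scores[, 2L])
  grid <- seq(min(fit_df$pc1), max(fit_df$pc1), length.out = n_grid)
  lo <- tryCatch(
    suppressWarnings(stats::loess(pc2 ~ pc1, data = fit_df, span = span,
                                  degree = 2, family = "gaussian",
                                  control = stats::loess.control(surface = "direct"))),
    error = function(e) NULL)
  pc2_hat <- if (!is.null(lo)) {
    suppressWarnings(as.numeric(stats::predict(lo, data.frame(pc1 = grid))))
  } else {
    # degenerate loess (very small n): quadratic least squares on the same axis
    qf <- stats::lm(pc2 ~ stats::poly(pc1, degree = min(2L, nrow(fit_df) - 2L),
                                      raw = TRUE), data = fit_df)
    as.numeric(stats::predict(qf, data.frame(pc1 = grid)))
  }
  spline_points <- cbind(pc1 = grid, pc2 = pc2_hat)
  arc_lengths <- c(0, cumsum(sqrt(diff(grid)^2 + diff(pc2_hat)^2)))

  model <- structure(list(genes = rownames(X), gene_means = unname(mu),
                          gene_sds = unname(sd_g), pc_loadings = unname(loadings),
                          spline_points = unname(spline_points),
                          arc_lengths = arc_lengths, span = span,
                          training_sample_ids = samples,
                          training_scores = unname(scores)),
                     class = "continuum_model")
  pl <- place_scores(model, scores, samples)
  anchor <- which(samples == sort(samples)[1L])
  if (pl$normalized[anchor] > 0.5) {
    model$spline_points <- model$spline_points[rev(seq_len(n_grid)), , drop = FALSE]
    steps <- sqrt(rowSums(diff(model$spline_points)^2))
    model$arc_lengths <- c(0, cumsum(steps))
    pl <- place_scores(model, scores, samples)
  }
  model$training_placements <- pl
  model
}

#' @export
print.continuum_model <- function(x, ...) {
  cat(sprintf("<continuum_model> %d genes, %d training samples, arc length %.3g (span %.2f)\n",
              length(x$genes), length(x$training_sample_ids),
              max(x$arc_lengths), x$span))
  invisible(x)
}

# Map (pc1, pc2) score rows to nearest spline vertices. Ties resolved to the
# lower arc length (first index).
place_scores <- function(model, scores, ids) {
  sp <- model$spline_points
  total <- max(model$arc_lengths)
  out <- data.frame(sample_id = ids, coordinate = NA_real_, normalized = NA_real_,
                    residual_distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(scores))) {
    d2 <- (sp[, 1L] - scores[i, 1L])^2 + (sp[, 2L] - scores[i, 2L])^2
    j <- which.min(d2)
    out$coordinate[i] <- model$arc_lengths[j]
    out$residual_distance[i] <- sqrt(d2[j])
  }
  out$normalized <- out$coordinate / total
  out
}

#' Place expression profiles on a fitted continuum
#'
#' Profiles are standardized with the training per-gene means and standard
#' deviations (model genes missing from the input are imputed at the
#' training mean, i.e. z = 0, with the imputed fraction recorded), projected
#' onto the training PC loadings, and assigned the arc length of the nearest
#' spline vertex (Euclidean distance; ties go to the lower arc length).
#'
#' @param model a [fit_continuum()] result.
#' @param profiles an [expression_matrix()] on the same expression scale as
#'   the training pseudobulk; must contain at least 50% of the model genes.
#' @return data.frame with `sample_id`, `coordinate`, `normalized`
#'   (`coordinate / total arc length`), `residual_distance`; attribute
#'   `imputed_fraction` gives the fraction of model genes imputed.
#' @export
place_on_continuum <- function(model, profiles) {
  stopifnot(inherits(model, "continuum_model"), inherits(profiles, "expr_matrix"))
  overlap <- mean(model$genes %in% em_genes(profiles))
  if (overlap < 0.5) {
    stop(sprintf("profiles contain only %.0f%% of model genes (need >= 50%%)",
                 100 * overlap))
  }
  V <- matrix(rep(model$gene_means, ncol(profiles$values)),
              nrow = length(model$genes),
              dimnames = list(model$genes, em_units(profiles)))
  shared <- intersect(model$genes, em_genes(profiles))
  V[shared, ] <- profiles$values[shared, , drop = FALSE]
  Z <- (V - model$gene_means) / model$gene_sds
  scores <- t(Z) %*% model$pc_loadings
  out <- place_scores(model, scores, em_units(profiles))
  attr(out, "imputed_fraction") <- 1 - overlap
  out
}

#' Immune-fraction trends along the continuum
#'
#' For each immune population, the Spearman correlation between its
#' per-sample fraction and the normalized continuum coordinate, plus a
#' loess-smoothed curve sampled at `n_grid` points. Constant fractions are
#' defined to have `rho = 0`, `p = 1`.
#'
#' @param placements data.frame from [place_on_continuum()] (or the model's
#'   `training_placements`).
#' @param fractions data.frame with a `sample_id` column and one numeric
#'   column in `[0, 1]` per population.
#' @param span loess span for the smoothed curve (default 0.75).
#' @param n_grid grid size for the smoothed curve (default 50).
#' @return list with `stats` (data.frame `population`, `rho`, `p`, `n`) and
#'   `curves` (data.frame `population`, `normalized`, `fitted`).
#' @export
fraction_trend <- function(placements, fractions, span = 0.75, n_grid = 50L) {
  stopifnot(is.data.frame(placements), is.data.frame(fractions),
            "sample_id" %in% names(fractions))
  df <- merge(placements[, c("sample_id", "normalized")], fractions,
              by = "sample_id")
  if (nrow(df) < 3L) stop("need at least 3 placed samples with fractions")
  pops <- setdiff(names(fractions), "sample_id")
  stats_rows <- list(); curve_rows <- list()
  grid <- seq(min(df$normalized), max(df$normalized), length.out = n_grid)
  for (pop in pops) {
    f <- df[[pop]]
    if (any(f < 0 | f > 1)) stop("fraction outside [0, 1] for population ", pop)
    st <- spearman_test(df$normalized, f)
    stats_rows[[pop]] <- data.frame(population = pop, rho = st$rho, p = st$p,
                                    n = st$n, stringsAsFactors = FALSE)
    cdat <- data.frame(x = df$normalized, f = f)
    lo <- tryCatch(
      suppressWarnings(stats::loess(f ~ x, data = cdat, span = span, degree = 2,
                                    control = stats::loess.control(surface = "direct"))),
      error = function(e) NULL)
    fitted <- if (!is.null(lo)) {
      suppressWarnings(as.numeric(stats::predict(lo, data.frame(x = grid))))
    } else {
      as.numeric(stats::predict(stats::lm(f ~ x, data = cdat),
                                data.frame(x = grid)))
    }
    curve_rows[[pop]] <- data.frame(population = pop, normalized = grid,
                                    fitted = fitted, stringsAsFactors = FALSE)
  }
  list(stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
       curves = do.call(rbind, c(curve_rows, list(make.row.names = FALSE))))
}

#' Serialize a continuum model to JSON
#'
#' Versioned schema so fitted models can be exchanged as plain text.
#'
#' @param model a [fit_continuum()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_continuum_model <- function(model, path) {
  stopifnot(inherits(model, "continuum_model"))
  payload <- list(schema = "epimm_continuum_model",
                  schema_version = 1L,
                  package_version = as.character(utils::packageVersion("epimm")),
                  genes = model$genes, gene_means = model$gene_means,
                  gene_sds = model$gene_sds,
                  pc_loadings = model$pc_loadings,
                  spline_points = model$spline_points,
                  arc_lengths = model$arc_lengths, span = model$span,
                  training_sample_ids = model$training_sample_ids,
                  training_scores = model$training_scores)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a continuum model from JSON
#' @param path a file written by [write_continuum_model()].
#' @return a `"continuum_model"` object.
#' @export
read_continuum_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "epimm_continuum_model")) {
    stop("not an epimm continuum model file: ", path)
  }
  model <- structure(list(genes = payload$genes,
                          gene_means = payload$gene_means,
                          gene_sds = payload$gene_sds,
                          pc_loadings = as.matrix(payload$pc_loadings),
                          spline_points = as.matrix(payload$spline_points),
                          arc_lengths = payload$arc_lengths,
                          span = payload$span,
                          training_sample_ids = payload$training_sample_ids,
                          training_scores = as.matrix(payload$training_scores)),
                     class = "continuum_model")
  model$training_placements <- place_scores(model, model$training_scores,
                                            model$training_sample_ids)
  model
}
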
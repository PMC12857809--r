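#' Simulate a two-type spatial ROI with tunable mixing
#'
#' Generates epithelial and immune cells on a square field. At `mixing = 0`
#' the two types are drawn from two well-separated Gaussian clusters (centre
#' distance at least `4 * cluster_sd + 50` micrometres, so no across-type
#' Delaunay edge survives a 50-micrometre prune); at `mixing = 1` both types
#' are uniform over the field; in between, each cell is placed from its
#' own-type cluster with probability `1 - mixing` and uniformly otherwise.
#' Bit-reproducible given the configuration and seed.
#'
#' @param n_epi,n_imm cell counts per type (>= 1).
#' @param mixing contamination probability lambda in `[0, 1]`.
#' @param field_size side of the square field in micrometres (default 1000).
#' @param cluster_sd Gaussian cluster standard deviation in micrometres
#'   (default 20).
#' @param seed integer seed.
#' @param roi_id ROI identifier (default `"sim_roi"`).
#' @return a [cell_table()] with types `"EPI"` and `"IMM"`.
#' @export
simulate_spatial_roi <- function(n_epi, n_imm, mixing, field_size = 1000,
                                 cluster_sd = 20, seed = 1L,
                                 roi_id = "sim_roi") {
  stopifnot(n_epi >= 1L, n_imm >= 1L, mixing >= 0, mixing <= 1,
            field_size > 0, cluster_sd > 0)
  sep <- 4 * cluster_sd + 50
  if (field_size < sep + 4 * cluster_sd) {
    stop("field too small to separate clusters: need at least ",
         sep + 4 * cluster_sd, " um")
  }
  centers <- rbind(EPI = c(field_size / 2 - sep / 2, field_size / 2),
                   IMM = c(field_size / 2 + sep / 2, field_size / 2))
  draw <- function(n, type) {
    uniform <- stats::runif(n) < mixing
    x <- ifelse(uniform, stats::runif(n, 0, field_size),
                stats::rnorm(n, centers[type, 1L], cluster_sd))
    y <- ifelse(uniform, stats::runif(n, 0, field_size),
                stats::rnorm(n, centers[type, 2L], cluster_sd))
    data.frame(roi_id = roi_id,
               cell_id = sprintf("%s_%s_%04d", roi_id, type, seq_len(n)),
               x = x, y = y, cell_type = type, stringsAsFactors = FALSE)
  }
  df <- withr::with_seed(as.integer(seed), {
    rbind(draw(n_epi, "EPI"), draw(n_imm, "IMM"))
  })
  cell_table(df)
}

#' Simulate ROI-level expression coupled to spatial mixedness
#'
#' For each ROI in `cells`, builds the proximity graph, computes the
#' mixedness `eAB / NAB` (observed across-type edges over possible
#' across-type pairs), and generates region-level expression: panel ligands
#' in the epithelial region and receptors in the immune region follow
#' `base * exp(coupling * mixedness + noise)` with log-normal noise of
#' standard deviation `noise_sd`; filler genes are i.i.d. log-normal around
#' `base`.
#'
#' @param cells a [cell_table()]; may contain several ROIs.
#' @param panel an [lr_panel()].
#' @param coupling coupling strength kappa (>= 0).
#' @param base baseline expression level (default 10).
#' @param n_filler i.i.d. filler genes per matrix (default 20).
#' @param noise_sd log-scale noise standard deviation (default 0.1).
#' @param max_edge_len graph prune cutoff in micrometres (default 50).
#' @param type_a,type_b labels of the epithelial and immune compartments.
#' @param seed integer seed.
#' @return list with `epi` and `imm` ([expression_matrix()], one column per
#'   ROI, `norm_state = "arbitrary"`) and `mixedness` (named numeric).
#' @export
simulate_roi_expression <- function(cells, panel, coupling, base = 10,
                                    n_filler = 20L, noise_sd = 0.1,
                                    max_edge_len = 50, type_a = "EPI",
                                    type_b = "IMM", seed = 1L) {
  stopifnot(inherits(cells, "cell_table"), inherits(panel, "lr_panel"),
            coupling >= 0, base > 0)
  rois <- unique(cells$roi_id)
  mixed <- vapply(rois, function(roi) {
    g <- build_proximity_graph(cell_table(cells[cells$roi_id == roi, ]),
                               max_edge_len = max_edge_len)
    cc <- classify_edges(g, type_a, type_b)
    cc$eAB / (cc$nA * cc$nB)
  }, 0)
  ligands <- unique(panel$ligand)
  receptors <- unique(panel$receptor)
  fillers <- sprintf("FILLER%03d", seq_len(n_filler))
  gen <- function(signal_genes) {
    m <- matrix(0, nrow = length(signal_genes) + n_filler, ncol = length(rois),
                dimnames = list(c(signal_genes, fillers), rois))
    for (j in seq_along(rois)) {
      m[signal_genes, j] <- base * exp(coupling * mixed[j] +
                                         stats::rnorm(length(signal_genes), 0, noise_sd))
      m[fillers, j] <- base * exp(stats::rnorm(n_filler, 0, noise_sd))
    }
    expression_matrix(m, norm_state = "arbitrary")
  }
  out <- withr::with_seed(as.integer(seed), list(epi = gen(ligands),
                                                 imm = gen(receptors)))
  out$mixedness <- mixed
  out
}

#' Simulate a continuum cohort with known latent disease axis
#'
#' Samples receive evenly spaced latent positions `t` on `[0, 1]`
#' (`t_1 = 0`, `t_n = 1`). Two opposing gene modules shift linearly in `t`
#' on the log-mean scale: module-A genes increase by `effect_size * t`,
#' module-B genes decrease by the same amount; remaining genes are flat.
#' Counts are negative binomial with variance `mu + mu^2 / nb_dispersion`.
#' A designated immune population's fraction follows
#' `0.1 + 0.5 * t + Normal(0, noise_sd)` truncated to `[0, 1]`.
#'
#' @param n_samples number of samples (default 20).
#' @param cells_per_sample basal cells per sample (default 200).
#' @param n_genes genes per cell (default 100); must satisfy
#'   `2 * module_size <= n_genes`.
#' @param module_size genes per opposing module (default 15).
#' @param effect_size per-unit-`t` log-expression shift (default 1.5,
#'   natural-log scale; >= 0).
#' @param nb_dispersion negative-binomial dispersion (default 10).
#' @param noise_sd immune-fraction noise standard deviation (default 0.02).
#' @param seed integer seed.
#' @return list with `counts` (named list of genes x cells integer
#'   matrices), `true_t` (named vector), `fractions` (data.frame
#'   `sample_id`, `IMM_X`), `module_a`, `module_b` (gene id vectors).
#' @export
simulate_continuum_cohort <- function(n_samples = 20L, cells_per_sample = 200L,
                                      n_genes = 100L, module_size = 15L,
                                      effect_size = 1.5, nb_dispersion = 10,
                                      noise_sd = 0.02, seed = 1L) {
  stopifnot(n_samples >= 2L, cells_per_sample >= 1L, effect_size >= 0,
            2L * module_size <= n_genes, nb_dispersion > 0, noise_sd >= 0)
  genes <- sprintf("G%03d", seq_len(n_genes))
  module_a <- genes[seq_len(module_size)]
  module_b <- genes[module_size + seq_len(module_size)]
  samples <- sprintf("S%02d", seq_len(n_samples))
  t_true <- stats::setNames(seq(0, 1, length.out = n_samples), samples)

  withr::with_seed(as.integer(seed), {
    base_log_mu <- stats::setNames(stats::runif(n_genes, log(1), log(20)), genes)
    counts <- lapply(samples, function(s) {
      shift <- numeric(n_genes)
      names(shift) <- genes
      shift[module_a] <- effect_size * t_true[[s]]
      shift[module_b] <- -effect_size * t_true[[s]]
      mu <- exp(base_log_mu + shift)
      m <- matrix(stats::rnbinom(n_genes * cells_per_sample,
                                 mu = rep(mu, cells_per_sample),
                                 size = nb_dispersion),
                  nrow = n_genes,
                  dimnames = list(genes,
                                  sprintf("%s_c%04d", s, seq_len(cells_per_sample))))
      m
    })
    names(counts) <- samples
    frac <- pmin(pmax(0.1 + 0.5 * t_true + stats::rnorm(n_samples, 0, noise_sd), 0), 1)
    list(counts = counts, true_t = t_true,
         fractions = data.frame(sample_id = samples, IMM_X = unname(frac),
                                stringsAsFactors = FALSE),
         module_a = module_a, module_b = module_b)
  })
}

#' Fit the basal transition continuum from per-sample count matrices
#'
#' The full continuum pipeline on raw counts: per-cell log-CPM
#' normalization, per-sample Wilcoxon DE of each non-reference sample
#' against the reference sample's cells (the package's single DE engine;
#' log2 fold changes derived from natural-log differences), continuum gene
#' selection with the cell-count / adjusted-p / `|log2FC|` / recurrence
#' filters, per-sample pseudobulk (mean log-CPM over selected genes), and
#' [fit_continuum()].
#'
#' @param counts named list of genes x cells raw count matrices, one per
#'   sample.
#' @param reference name of the reference (control-like) sample; defaults
#'   to the first.
#' @param min_cells,max_padj,min_abs_lfc,min_samples see
#'   [select_continuum_genes()].
#' @param span loess span for [fit_continuum()].
#' @return list with `model` (a `"continuum_model"`), `genes` (the selected
#'   [gene_set()]), `pseudobulk` (the [expression_matrix()] used), and
#'   `de_tables`.
#' @export
continuum_from_counts <- function(counts, reference = names(counts)[1L],
                                  min_cells = 50L, max_padj = 0.05,
                                  min_abs_lfc = 0.5, min_samples = 2L,
                                  span = 0.75) {
  stopifnot(is.list(counts), !is.null(names(counts)),
            reference %in% names(counts))
  logn <- lapply(counts, function(m) normalize_log_cpm(expression_matrix(m)))
  ref <- logn[[reference]]
  others <- setdiff(names(counts), reference)
  de_tables <- lapply(others, function(s) {
    em <- expression_matrix(cbind(logn[[s]]$values, ref$values),
                            norm_state = "log_cpm")
    tab <- rank_de_test(em, group_a = em_units(logn[[s]]), group_b = em_units(ref),
                        min_lfc = 0, min_pct = 0, correction = "bh")
    data.frame(gene = tab$gene, p = tab$p, log2_fc = tab$log_fc / log(2),
               stringsAsFactors = FALSE)
  })
  names(de_tables) <- others
  n_cells <- vapply(counts, ncol, 0L)
  genes <- select_continuum_genes(de_tables, n_cells[others],
                                  min_cells = min_cells, max_padj = max_padj,
                                  min_abs_lfc = min_abs_lfc,
                                  min_samples = min_samples)
  pb <- vapply(names(counts), function(s) {
    rowMeans(logn[[s]]$values[genes$genes, , drop = FALSE])
  }, numeric(length(genes$genes)))
  pseudobulk <- expression_matrix(pb, genes$genes, names(counts),
                                  norm_state = "arbitrary")
  list(model = fit_continuum(pseudobulk, span = span), genes = genes,
       pseudobulk = pseudobulk, de_tables = de_tables)
}
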
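#' Binned-control module score
#'
#' Re-implementation of the binned-control signature score used for
#' single-cell data: genes are placed into `n_bins` equal-frequency bins by
#' their average expression across units; for each signature gene, `n_ctrl`
#' control genes are sampled with replacement from that gene's bin; the score
#' of a unit is the mean expression of the signature genes minus the mean
#' expression of the pooled control draws. Scores are shift-invariant (a
#' global additive constant cancels) and reproducible under a fixed seed.
#'
#' Sampling order is part of the contract: the stream is seeded once, then
#' control genes are drawn for each present signature gene in panel order.
#'
#' @param em a log-scale [expression_matrix()].
#' @param sig a [gene_set()]; at least one gene must be present in the
#'   matrix. Signature genes absent from the matrix are dropped.
#' @param n_bins number of expression bins (default 24); the matrix must
#'   have more genes than bins.
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for control sampling.
#' @return object of class `"signature_scores"`: list with `signature`,
#'   `unit_ids`, `scores`, `method = "module_score"`, `params`.
#' @export
module_score <- function(em, sig, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  stopifnot(inherits(em, "expr_matrix"), inherits(sig, "gene_set"))
  genes <- em_genes(em)
  if (length(genes) <= n_bins) stop("matrix must have more genes than bins")
  present <- sig$genes[sig$genes %in% genes]
  if (!length(present)) {
    stop("no signature gene present in matrix; missing: ",
         paste(sig$genes, collapse = ", "))
  }
  avg <- rowMeans(em$values)
  # equal-frequency bins on the rank of average expression
  bin <- as.integer(cut(rank(avg, ties.method = "first"), breaks = n_bins,
                        labels = FALSE, include.lowest = TRUE))
  names(bin) <- genes
  ctrl_idx <- with_stream_seed(seed, sig$name, {
    unlist(lapply(present, function(gg) {
      pool <- which(bin == bin[[gg]])
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  sig_mean <- colMeans(em$values[present, , drop = FALSE])
  ctrl_mean <- colMeans(em$values[ctrl_idx, , drop = FALSE])
  structure(list(signature = sig$name, unit_ids = em_units(em),
                 scores = unname(sig_mean - ctrl_mean), method = "module_score",
                 params = list(n_bins = as.integer(n_bins),
                               n_ctrl = as.integer(n_ctrl),
                               seed = as.integer(seed))),
            class = "signature_scores")
}

#' Single-sample rank-enrichment (ssGSEA-style) score
#'
#' Per unit, genes are ranked by expression (ties get average ranks) and
#' walked from highest to lowest. At each position the running sum adds the
#' weighted in-set cumulative fraction (weights `rank^alpha` for in-set
#' genes) minus the uniform out-of-set cumulative fraction; the score is the
#' sum over all positions. Depends on expression only through ranks, so it
#' is invariant to any strictly monotone per-unit transform.
#'
#' @param em an [expression_matrix()] (any `norm_state`).
#' @param sig a [gene_set()]; its intersection with the matrix genes must be
#'   a non-empty proper subset (an all-gene signature has an empty
#'   complement and is an error).
#' @param alpha rank-weighting exponent (default 0.25; `alpha = 0` gives the
#'   unweighted KS-style statistic).
#' @return a `"signature_scores"` object with `method = "ssgsea"`.
#' @export
ssgsea_score <- function(em, sig, alpha = 0.25) {
  stopifnot(inherits(em, "expr_matrix"), inherits(sig, "gene_set"))
  genes <- em_genes(em)
  inset <- genes %in% sig$genes
  if (!any(inset)) {
    stop("no signature gene present in matrix; missing: ",
         paste(sig$genes, collapse = ", "))
  }
  if (all(inset)) stop("signature covers all matrix genes; complement is empty")
  n <- length(genes)
  n_out <- sum(!inset)
  scores <- apply(em$values, 2L, function(v) {
    r <- rank(v, ties.method = "average")
    ord <- order(v, decreasing = TRUE)  # ties broken by gene index, stable
    in_ord <- inset[ord]
    w <- ifelse(in_ord, r[ord]^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_ord) / n_out
    sum(p_in - p_out)
  })
  structure(list(signature = sig$name, unit_ids = em_units(em),
                 scores = unname(scores), method = "ssgsea",
                 params = list(alpha = alpha)),
            class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("<signature_scores> '%s' (%s): %d units, range [%.3g, %.3g]\n",
              x$signature, x$method, length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Signature scores as a data.frame
#' @param x a `"signature_scores"` object.
#' @param ... unused.
#' @return data.frame with `unit_id`, `signature`, `score`.
#' @export
as.data.frame.signature_scores <- function(x, ...) {
  data.frame(unit_id = x$unit_ids, signature = x$signature, score = x$scores,
             stringsAsFactors = FALSE)
}

#' Threshold-filtered Wilcoxon rank-sum marker test
#'
#' Marker-style differential expression between two groups of units on
#' log-scale values. Genes are pre-filtered on effect size and detection
#' rate -- only genes with `|log_fc| > min_lfc` (difference of group means of
#' log-normalized values, natural-log scale) and detectable in more than
#' `min_pct` of units in at least one group are tested -- then the two-sided
#' Wilcoxon rank-sum test is applied, with multiple-testing correction over
#' the tested genes only.
#'
#' @param em a log-scale [expression_matrix()].
#' @param group_a,group_b disjoint vectors of unit ids, each with >= 2
#'   units.
#' @param min_lfc pre-filter on `|log_fc|` (default 0.25, exclusive).
#' @param min_pct pre-filter on `max(pct_a, pct_b)` (default 0.25,
#'   exclusive); `pct` is the fraction of units with value > 0.
#' @param correction `"bonferroni"` (default, as used for marker selection)
#'   or `"bh"`.
#' @return data.frame of class `"de_table"` with columns `gene`, `log_fc`
#'   (group A minus group B), `pct_a`, `pct_b`, `p`, `p_adj`, sorted by `p`;
#'   attributes `method = "wilcoxon"` and `correction`.
#' @export
rank_de_test <- function(em, group_a, group_b, min_lfc = 0.25, min_pct = 0.25,
                         correction = c("bonferroni", "bh")) {
  stopifnot(inherits(em, "expr_matrix"))
  correction <- match.arg(correction)
  units <- em_units(em)
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), units)
  if (length(missing)) stop("unknown unit id(s): ", paste(missing, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 units")
  }
  A <- em$values[, group_a, drop = FALSE]
  B <- em$values[, group_b, drop = FALSE]
  log_fc <- rowMeans(A) - rowMeans(B)
  pct_a <- rowMeans(A > 0)
  pct_b <- rowMeans(B > 0)
  keep <- abs(log_fc) > min_lfc & pmax(pct_a, pct_b) > min_pct
  genes <- em_genes(em)[keep]
  p <- vapply(which(keep), function(i) {
    suppressWarnings(stats::wilcox.test(A[i, ], B[i, ],
                                        alternative = "two.sided")$p.value)
  }, 0)
  out <- data.frame(gene = genes, log_fc = log_fc[keep], pct_a = pct_a[keep],
                    pct_b = pct_b[keep], p = p,
                    p_adj = stats::p.adjust(p, method = if (correction == "bh") "BH"
                                            else "bonferroni"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "wilcoxon"
  attr(out, "correction") <- correction
  class(out) <- c("de_table", "data.frame")
  out
}

#' Spearman correlation of two signature scores across paired regions
#'
#' Pairs the two score vectors by unit id (optionally through an explicit
#' mapping, e.g. epithelial ROI -> matched immune ROI of the same tissue)
#' and computes tie-corrected Spearman rho with a two-sided p-value: the t
#' approximation for `n >= 10`, exact permutation enumeration for `n < 10`.
#'
#' @param scores_a,scores_b `"signature_scores"` objects.
#' @param pairing optional named character vector mapping unit ids of
#'   `scores_a` to unit ids of `scores_b`; by default units are matched by
#'   identical id.
#' @return list with `rho`, `p`, `n`.
#' @export
region_score_correlation <- function(scores_a, scores_b, pairing = NULL) {
  stopifnot(inherits(scores_a, "signature_scores"),
            inherits(scores_b, "signature_scores"))
  a <- stats::setNames(scores_a$scores, scores_a$unit_ids)
  b <- stats::setNames(scores_b$scores, scores_b$unit_ids)
  if (is.null(pairing)) {
    shared <- intersect(names(a), names(b))
    pairing <- stats::setNames(shared, shared)
  }
  keep <- names(pairing) %in% names(a) & pairing %in% names(b)
  pairing <- pairing[keep]
  if (length(pairing) < 3L) {
    stop("need at least 3 paired ROIs, got ", length(pairing))
  }
  spearman_test(a[names(pairing)], b[unname(pairing)])
}
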
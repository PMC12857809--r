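#' Interaction odds, odds ratios, and the geometric odds ratio OR*
#'
#' From observed within- and across-type edge counts on a proximity graph,
#' compute the interaction odds
#' `Odds_XY = e_XY / (N_XY - e_XY)` where `N_AB = nA*nB`,
#' `N_AA = nA(nA-1)/2`, `N_BB = nB(nB-1)/2` are the total possible pairs,
#' the odds ratios `OR_AB/AA = Odds_AB / Odds_AA` and
#' `OR_AB/BB = Odds_AB / Odds_BB`, and the geometric odds ratio
#' `OR* = sqrt(OR_AB/AA * OR_AB/BB)`, the across-type odds against the
#' geometric mean of the two within-type odds.
#'
#' Degeneracy policy: whenever any observed count equals 0 or its maximum, or
#' any denominator `N` is 0, the Haldane-Anscombe correction
#' `odds = (e + 0.5) / (N - e + 0.5)` is applied to all three odds and
#' `corrected = TRUE` is recorded; applying it to all three preserves the
#' A-B label symmetry of OR*. Uncorrected odds (possibly 0, `Inf`, or `NaN`)
#' are retained in `uncorrected` for transparency.
#'
#' @param counts an [edge_counts()] (or [classify_edges()] result). Optional
#'   elements `NAA`, `NBB`, `NAB` override the denominators computed from
#'   `nA`, `nB`; [pool_edge_counts()] uses this so that pooled denominators
#'   exclude cross-ROI pairs.
#' @return object of class `"odds_result"`: list with `roi_id`, `nA`, `nB`,
#'   `NAA`, `NBB`, `NAB`, `odds_AA`, `odds_BB`, `odds_AB` (post-correction
#'   when triggered), `OR_AB_AA`, `OR_AB_BB`, `or_star`, `corrected`, and
#'   `uncorrected` (list of the three raw odds and raw `or_star`).
#' @export
compute_interaction_odds <- function(counts) {
  stopifnot(inherits(counts, "edge_counts"))
  nA <- counts$nA; nB <- counts$nB
  if (nA < 1L || nB < 1L) stop("both cell types must have at least one cell")
  NAB <- counts$NAB %||% (nA * nB)
  NAA <- counts$NAA %||% (nA * (nA - 1) / 2)
  NBB <- counts$NBB %||% (nB * (nB - 1) / 2)
  e <- c(AA = counts$eAA, BB = counts$eBB, AB = counts$eAB)
  N <- c(AA = NAA, BB = NBB, AB = NAB)
  if (any(e > N)) stop("observed count exceeds possible pairs: ",
                       paste(names(e)[e > N], collapse = ", "))

  raw <- e / (N - e)  # 0/0 -> NaN, e = N > 0 -> Inf
  raw_or_star <- raw[["AB"]] / sqrt(raw[["AA"]] * raw[["BB"]])

  degenerate <- any(e == 0 | e == N | N == 0)
  odds <- if (degenerate) (e + 0.5) / (N - e + 0.5) else raw

  or_ab_aa <- odds[["AB"]] / odds[["AA"]]
  or_ab_bb <- odds[["AB"]] / odds[["BB"]]
  structure(list(roi_id = counts$roi_id, type_a = counts$type_a,
                 type_b = counts$type_b, nA = nA, nB = nB,
                 NAA = NAA, NBB = NBB, NAB = NAB,
                 eAA = counts$eAA, eBB = counts$eBB, eAB = counts$eAB,
                 odds_AA = odds[["AA"]], odds_BB = odds[["BB"]],
                 odds_AB = odds[["AB"]],
                 OR_AB_AA = or_ab_aa, OR_AB_BB = or_ab_bb,
                 or_star = sqrt(or_ab_aa * or_ab_bb),
                 corrected = degenerate,
                 uncorrected = list(odds_AA = raw[["AA"]], odds_BB = raw[["BB"]],
                                    odds_AB = raw[["AB"]], or_star = raw_or_star)),
            class = "odds_result")
}

#' @export
print.odds_result <- function(x, ...) {
  cat(sprintf("<odds_result> ROI %s: OR* = %.4g%s (eAB=%d/%g, eAA=%d/%g, eBB=%d/%g)\n",
              x$roi_id, x$or_star, if (x$corrected) " [corrected]" else "",
              x$eAB, x$NAB, x$eAA, x$NAA, x$eBB, x$NBB))
  invisible(x)
}

#' Pool edge counts across ROIs of one individual
#'
#' Sums the observed counts, node counts, and per-ROI possible-pair
#' denominators. Denominators are summed per ROI (rather than recomputed from
#' the summed node counts) so that pairs spanning two ROIs, which can never
#' be edges, do not enter the odds.
#'
#' @param counts_list list of [edge_counts()] objects with matching labels.
#' @param roi_id id for the pooled result.
#' @return an `"edge_counts"` object carrying explicit `NAA`, `NBB`, `NAB`.
#' @export
pool_edge_counts <- function(counts_list, roi_id = "pooled") {
  stopifnot(length(counts_list) >= 1L,
            all(vapply(counts_list, inherits, TRUE, "edge_counts")))
  ta <- unique(vapply(counts_list, `[[`, "", "type_a"))
  tb <- unique(vapply(counts_list, `[[`, "", "type_b"))
  if (length(ta) != 1L || length(tb) != 1L) stop("mismatched type labels across ROIs")
  tot <- function(f) sum(vapply(counts_list, function(cc) as.double(cc[[f]]), 0))
  out <- edge_counts(tot("nA"), tot("nB"), tot("eAA"), tot("eBB"), tot("eAB"),
                     roi_id = roi_id, type_a = ta, type_b = tb)
  out$NAA <- sum(vapply(counts_list, function(cc) cc$nA * (cc$nA - 1) / 2, 0))
  out$NBB <- sum(vapply(counts_list, function(cc) cc$nB * (cc$nB - 1) / 2, 0))
  out$NAB <- sum(vapply(counts_list, function(cc) as.double(cc$nA) * cc$nB, 0))
  out
}

#' Permutation null for OR* under random labeling
#'
#' Holds the proximity graph fixed and permutes the cell-type labels
#' uniformly at random over all nodes `n_perm` times, recomputing OR* (same
#' correction policy as [compute_interaction_odds()]) each time. The
#' empirical one-sided p-value uses the add-one convention
#' `p = (1 + #\{OR*_perm >= OR*_obs\}) / (1 + n_perm)`, which can never be
#' zero. The random stream is keyed by `(seed, roi_id)` so ROIs are
#' independent and runs reproducible.
#'
#' @param g a [build_proximity_graph()] result.
#' @param type_a,type_b the two labels whose interaction is scored.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer base seed.
#' @return object of class `"null_distribution"`: list with `roi_id`,
#'   `n_perm`, `seed`, `or_star_samples`, `observed_or_star`, `empirical_p`.
#' @export
permutation_null <- function(g, type_a, type_b, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(g, "spatial_graph"))
  if (n_perm < 1L) stop("n_perm must be at least 1")
  types <- g$nodes$cell_type
  if (length(unique(types)) < 2L) stop("fewer than 2 labels present in ROI ", g$roi_id)
  observed <- compute_interaction_odds(classify_edges(g, type_a, type_b))$or_star
  ia <- g$edges$ia
  ib <- g$edges$ib
  nA <- sum(types == type_a)
  nB <- sum(types == type_b)
  samples <- with_stream_seed(seed, g$roi_id, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(types)
      ta <- lab[ia]; tb <- lab[ib]
      cc <- edge_counts(nA, nB,
                        eAA = sum(ta == type_a & tb == type_a),
                        eBB = sum(ta == type_b & tb == type_b),
                        eAB = sum((ta == type_a & tb == type_b) |
                                    (ta == type_b & tb == type_a)),
                        roi_id = g$roi_id, type_a = type_a, type_b = type_b)
      compute_interaction_odds(cc)$or_star
    }, 0)
  })
  structure(list(roi_id = g$roi_id, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), or_star_samples = samples,
                 observed_or_star = observed,
                 empirical_p = (1 + sum(samples >= observed)) / (1 + n_perm)),
            class = "null_distribution")
}
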
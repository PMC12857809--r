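# Independent oracles and fixture builders used across the suite. These are
# deliberately written as plain loops / direct formula transcriptions so that
# they share no code path with the package implementation they check.

# Delaunay edge test by the empty-circumcircle characterization: (i, j) is a
# Delaunay edge iff some circle through both points contains no other point.
# Centers on the perpendicular bisector are parameterized by t; each other
# point q imposes a linear constraint a_q + b_q * t > 0 on t, and the edge
# exists iff the constraints have a common solution.
delaunay_edge_oracle <- function(x, y, i, j) {
  m <- c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2)
  d <- c(x[j] - x[i], y[j] - y[i])
  u <- c(-d[2L], d[1L]) / sqrt(sum(d^2))
  lo <- -Inf; hi <- Inf
  pi2 <- (x[i] - m[1L])^2 + (y[i] - m[2L])^2
  for (q in seq_along(x)) {
    if (q == i || q == j) next
    a <- (x[q] - m[1L])^2 + (y[q] - m[2L])^2 - pi2
    b <- -2 * ((x[q] - m[1L]) * u[1L] + (y[q] - m[2L]) * u[2L])
    if (abs(b) < 1e-12) {
      if (a <= 0) return(FALSE)
    } else if (b > 0) {
      lo <- max(lo, -a / b)
    } else {
      hi <- min(hi, -a / b)
    }
  }
  lo < hi - 1e-12
}

# Brute-force O(n^2) classification: scan every node pair, check membership
# in the graph's edge set, and tally by the two requested labels.
brute_force_classify <- function(g, type_a, type_b) {
  n <- nrow(g$nodes)
  key <- paste(g$edges$ia, g$edges$ib)
  types <- g$nodes$cell_type
  eAA <- eBB <- eAB <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!(paste(i, j) %in% key)) next
      ti <- types[i]; tj <- types[j]
      if (ti == type_a && tj == type_a) eAA <- eAA + 1L
      else if (ti == type_b && tj == type_b) eBB <- eBB + 1L
      else if ((ti == type_a && tj == type_b) || (ti == type_b && tj == type_a))
        eAB <- eAB + 1L
    }
  }
  list(nA = sum(types == type_a), nB = sum(types == type_b),
       eAA = eAA, eBB = eBB, eAB = eAB)
}

# Direct transcription of the displayed odds formulas, including the
# all-three Haldane-Anscombe correction policy.
direct_odds <- function(nA, nB, eAA, eBB, eAB) {
  NAB <- nA * nB
  NAA <- nA * (nA - 1) / 2
  NBB <- nB * (nB - 1) / 2
  degenerate <- eAB == 0 || eAB == NAB || eAA == 0 || eAA == NAA ||
    eBB == 0 || eBB == NBB || NAB == 0 || NAA == 0 || NBB == 0
  if (degenerate) {
    oAB <- (eAB + 0.5) / (NAB - eAB + 0.5)
    oAA <- (eAA + 0.5) / (NAA - eAA + 0.5)
    oBB <- (eBB + 0.5) / (NBB - eBB + 0.5)
  } else {
    oAB <- eAB / (NAB - eAB)
    oAA <- eAA / (NAA - eAA)
    oBB <- eBB / (NBB - eBB)
  }
  list(odds_AB = oAB, odds_AA = oAA, odds_BB = oBB,
       or_star = sqrt((oAB / oAA) * (oAB / oBB)), corrected = degenerate)
}

# Step-by-step module score: same sampling contract (stream seeded once,
# draws per signature gene in panel order), written as an explicit loop.
module_score_oracle <- function(em, sig, n_bins, n_ctrl, seed) {
  vals <- em$values
  genes <- rownames(vals)
  avg <- apply(vals, 1L, mean)
  bin <- as.integer(cut(rank(avg, ties.method = "first"), breaks = n_bins,
                        labels = FALSE, include.lowest = TRUE))
  present <- sig$genes[sig$genes %in% genes]
  ctrl <- integer(0)
  withr::with_seed(epimm:::derive_seed(seed, sig$name), {
    for (gg in present) {
      pool <- which(bin == bin[[match(gg, genes)]])
      ctrl <- c(ctrl, pool[sample.int(length(pool), n_ctrl, replace = TRUE)])
    }
  })
  out <- numeric(ncol(vals))
  for (u in seq_len(ncol(vals))) {
    out[u] <- mean(vals[present, u]) - mean(vals[ctrl, u])
  }
  out
}

# Step-by-step rank-enrichment running sum per unit.
ssgsea_oracle <- function(em, sig, alpha) {
  vals <- em$values
  genes <- rownames(vals)
  out <- numeric(ncol(vals))
  for (u in seq_len(ncol(vals))) {
    v <- vals[, u]
    r <- rank(v, ties.method = "average")
    ord <- order(v, decreasing = TRUE)
    inset <- genes[ord] %in% sig$genes
    w_total <- sum(r[ord][inset]^alpha)
    n_out <- sum(!inset)
    p_in <- 0; p_out <- 0; es <- 0
    for (k in seq_along(ord)) {
      if (inset[k]) p_in <- p_in + r[ord][k]^alpha / w_total
      else p_out <- p_out + 1 / n_out
      es <- es + (p_in - p_out)
    }
    out[u] <- es
  }
  out
}

# Exhaustive permutation distribution of Spearman rho (classic d^2 formula;
# valid for untied data), independent of the package's internals.
spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(r1, r2) 1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
  obs <- rho_of(rx, ry)
  perm_rhos <- c()
  gen <- function(prefix, remaining) {
    if (!length(remaining)) {
      perm_rhos <<- c(perm_rhos, rho_of(rx, ry[prefix]))
      return(invisible())
    }
    for (k in remaining) gen(c(prefix, k), setdiff(remaining, k))
  }
  gen(integer(0), seq_len(n))
  list(rho = obs, p = mean(abs(perm_rhos) >= abs(obs) - 1e-12),
       n_perm = length(perm_rhos))
}

# Small expression-matrix builder with deterministic pseudo-random values.
make_expr <- function(n_genes, n_units, seed = 1, norm_state = "arbitrary") {
  withr::with_seed(seed, {
    m <- matrix(round(runif(n_genes * n_units, 0, 8), 3), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("u%02d", seq_len(n_units))))
    expression_matrix(m, norm_state = norm_state)
  })
}

# Random single-ROI cell table for graph property tests.
random_roi <- function(n, seed, field = 300, types = c("EPI", "IMM"),
                       roi_id = paste0("r", seed)) {
  withr::with_seed(seed, {
    lab <- sample(types, n, replace = TRUE)
    lab[seq_along(types)] <- types  # guarantee every type occurs
    cell_table(data.frame(
      roi_id = roi_id, cell_id = sprintf("c%03d", seq_len(n)),
      x = runif(n, 0, field), y = runif(n, 0, field),
      cell_type = lab, stringsAsFactors = FALSE))
  })
}
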
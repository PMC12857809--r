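# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible integer stream seed from a base seed and a string key
#'
#' Used so that per-ROI random streams (permutation nulls, jitter) are
#' independent across ROIs but fully determined by `(seed, key)`.
#'
#' @param seed integer base seed.
#' @param key character key (e.g. an ROI id).
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, key) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps the result a valid R integer
  h <- as.double(seed %% m)
  for (code in utf8ToInt(paste0(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a derived seed without disturbing the caller's RNG.
with_stream_seed <- function(seed, key, expr) {
  withr::with_seed(derive_seed(seed, key), expr)
}

# Geometric mean; any zero entry gives exactly zero (no pseudocount).
geometric_mean <- function(x) {
  stopifnot(all(x >= 0))
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# Provenance comment line written at the top of all TSV outputs.
provenance_header <- function(what, params = list()) {
  ver <- as.character(utils::packageVersion("epimm"))
  par <- if (length(params)) {
    paste(sprintf("%s=%s", names(params), vapply(params, format, "")), collapse = " ")
  } else ""
  sprintf("# epimm %s | %s | %s", ver, what, par)
}

# Write a data.frame as UTF-8 TSV with a commented provenance header.
write_tsv_provenance <- function(df, path, what, params = list()) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(what, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spearman correlation with exact small-sample p-value
#'
#' Tie-corrected Spearman rho. Two-sided p-value via the t approximation for
#' `n >= 10` and exhaustive permutation enumeration for `n < 10`. Degenerate
#' (zero-variance) inputs are defined to have `rho = 0`, `p = 1`.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p`, `n`.
#' @keywords internal
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearman_test requires at least 3 pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = 0, p = 1, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    rx <- rank(x)
    ry <- rank(y)
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

# All permutations of 1..n as an (n!) x n integer matrix. Only used for n < 10.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}
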
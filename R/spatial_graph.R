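#' Build a pruned Delaunay proximity graph for one ROI
#'
#' Cells become nodes; edges are Delaunay triangulation edges whose Euclidean
#' length does not exceed `max_edge_len` (inclusive), so that edges indicate a
#' proximity of at most `max_edge_len` micrometres. Degenerate inputs (fewer
#' than 3 cells, or all cells collinear) fall back to the complete graph
#' pruned at the same cutoff, so downstream edge counts stay defined. Exact
#' duplicate coordinates are jittered by 1e-6 micrometres under a seed derived
#' from the ROI id, and the jitter is recorded on the returned object.
#'
#' @param cells a [cell_table()] restricted to a single ROI.
#' @param max_edge_len edge-length cutoff in micrometres (default 50,
#'   inclusive).
#' @return object of class `"spatial_graph"`: list with `roi_id`, `nodes`
#'   (data.frame `cell_id`, `x`, `y`, `cell_type`), `edges` (data.frame of
#'   node indices `ia`, `ib` with `ia < ib`, ids `cell_a`, `cell_b`, and
#'   `length_um`), `max_edge_len`, and `jittered` (logical).
#' @export
build_proximity_graph <- function(cells, max_edge_len = 50) {
  stopifnot(inherits(cells, "cell_table"))
  if (max_edge_len <= 0) stop("max_edge_len must be positive")
  roi <- unique(cells$roi_id)
  if (length(roi) != 1L) {
    stop("build_proximity_graph expects a single ROI, got: ",
         paste(roi, collapse = ", "))
  }
  nodes <- data.frame(cell_id = cells$cell_id, x = cells$x, y = cells$y,
                      cell_type = cells$cell_type, stringsAsFactors = FALSE)
  n <- nrow(nodes)
  x <- nodes$x
  y <- nodes$y

  jittered <- FALSE
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    jittered <- TRUE
    idx <- which(dup)
    jit <- with_stream_seed(0L, roi, matrix(stats::runif(2L * length(idx), -1, 1),
                                            ncol = 2L)) * 1e-6
    x[idx] <- x[idx] + jit[, 1L]
    y[idx] <- y[idx] + jit[, 2L]
    message("ROI ", roi, ": ", length(idx),
            " duplicate coordinate(s) jittered by 1e-6 um")
  }

  collinear <- n >= 3L && {
    cx <- x - mean(x); cy <- y - mean(y)
    s <- svd(cbind(cx, cy), nu = 0, nv = 0)$d
    s[2L] <= max(s[1L], 1) * 1e-12
  }

  if (n < 3L || collinear) {
    pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(integer(), 0L, 2L)
  } else {
    dd <- deldir::deldir(x, y)
    pairs <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
  }
  if (nrow(pairs)) {
    ia <- pmin(pairs[, 1L], pairs[, 2L])
    ib <- pmax(pairs[, 1L], pairs[, 2L])
    len <- sqrt((x[ia] - x[ib])^2 + (y[ia] - y[ib])^2)
    keep <- len <= max_edge_len
    ord <- order(ia[keep], ib[keep])
    edges <- data.frame(ia = ia[keep][ord], ib = ib[keep][ord],
                        cell_a = nodes$cell_id[ia[keep][ord]],
                        cell_b = nodes$cell_id[ib[keep][ord]],
                        length_um = len[keep][ord], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(ia = integer(), ib = integer(), cell_a = character(),
                        cell_b = character(), length_um = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(roi_id = roi, nodes = nodes, edges = edges,
                 max_edge_len = max_edge_len, jittered = jittered),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> ROI %s: %d nodes, %d edges (cutoff %g um)\n",
              x$roi_id, nrow(x$nodes), nrow(x$edges), x$max_edge_len))
  invisible(x)
}

#' Classify proximity-graph edges by cell-type pair
#'
#' Counts within-type and across-type edges for two labels. Edges touching
#' any other cell type are ignored; node counts `nA`, `nB` are the numbers of
#' cells carrying each label.
#'
#' @param g a [build_proximity_graph()] result.
#' @param type_a,type_b distinct cell-type labels, both present in the ROI.
#' @return object of class `"edge_counts"`: list with `roi_id`, `type_a`,
#'   `type_b`, `nA`, `nB`, `eAA`, `eBB`, `eAB`.
#' @export
classify_edges <- function(g, type_a, type_b) {
  stopifnot(inherits(g, "spatial_graph"))
  if (identical(type_a, type_b)) stop("type_a and type_b must differ")
  types <- g$nodes$cell_type
  nA <- sum(types == type_a)
  nB <- sum(types == type_b)
  if (nA == 0L) stop("label '", type_a, "' absent from ROI ", g$roi_id)
  if (nB == 0L) stop("label '", type_b, "' absent from ROI ", g$roi_id)
  ta <- types[g$edges$ia]
  tb <- types[g$edges$ib]
  structure(list(roi_id = g$roi_id, type_a = type_a, type_b = type_b,
                 nA = nA, nB = nB,
                 eAA = sum(ta == type_a & tb == type_a),
                 eBB = sum(ta == type_b & tb == type_b),
                 eAB = sum((ta == type_a & tb == type_b) |
                             (ta == type_b & tb == type_a))),
            class = "edge_counts")
}

#' Construct edge counts directly
#'
#' For programmatic use (e.g. the worked examples and pooling); invariants
#' `eAA <= nA(nA-1)/2`, `eBB <= nB(nB-1)/2`, `eAB <= nA*nB` are enforced.
#'
#' @param nA,nB node counts per label (>= 0 integers).
#' @param eAA,eBB,eAB observed within- and across-type edge counts.
#' @param roi_id,type_a,type_b identifiers carried through to results.
#' @return an `"edge_counts"` object.
#' @export
edge_counts <- function(nA, nB, eAA, eBB, eAB, roi_id = "roi",
                        type_a = "A", type_b = "B") {
  vals <- c(nA = nA, nB = nB, eAA = eAA, eBB = eBB, eAB = eAB)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("edge counts must be non-negative integers")
  }
  if (eAA > nA * (nA - 1) / 2) stop("eAA exceeds nA(nA-1)/2")
  if (eBB > nB * (nB - 1) / 2) stop("eBB exceeds nB(nB-1)/2")
  if (eAB > nA * nB) stop("eAB exceeds nA*nB")
  structure(list(roi_id = roi_id, type_a = type_a, type_b = type_b,
                 nA = as.integer(nA), nB = as.integer(nB),
                 eAA = as.integer(eAA), eBB = as.integer(eBB),
                 eAB = as.integer(eAB)),
            class = "edge_counts")
}

#' Write the edge list of a spatial graph as TSV
#'
#' Columns: `roi_id`, `cell_a`, `cell_b`, `length_um`, `pair_class` (the
#' unordered pair of endpoint cell types, e.g. `"EPI-IMM"`).
#'
#' @param g a [build_proximity_graph()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "spatial_graph"))
  ta <- g$nodes$cell_type[g$edges$ia]
  tb <- g$nodes$cell_type[g$edges$ib]
  df <- data.frame(roi_id = g$roi_id, cell_a = g$edges$cell_a,
                   cell_b = g$edges$cell_b, length_um = g$edges$length_um,
                   pair_class = paste(pmin(ta, tb), pmax(ta, tb), sep = "-"),
                   stringsAsFactors = FALSE)
  write_tsv_provenance(df, path, "edge_list", list(cutoff_um = g$max_edge_len))
}
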
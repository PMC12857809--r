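#' Construct an expression matrix
#'
#' Genes-by-units expression container, where units are cells or ROIs. Keeps
#' a `norm_state` tag so downstream scoring knows whether values are raw
#' counts, log-CPM, or an externally normalized quantity.
#'
#' @param values numeric matrix, genes in rows, units in columns,
#'   non-negative.
#' @param gene_ids,unit_ids character vectors matching the matrix
#'   dimensions; both must be free of duplicates. Defaults to the dimnames
#'   of `values`.
#' @param norm_state one of `"raw_counts"`, `"log_cpm"`, `"arbitrary"`. If
#'   `NULL`, inferred as `"raw_counts"` when all entries are integral and
#'   `"arbitrary"` otherwise.
#' @return an object of class `"expr_matrix"`: a list with elements
#'   `values` (with dimnames set) and `norm_state`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              unit_ids = colnames(values), norm_state = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(unit_ids)) {
    stop("gene_ids and unit_ids are required when `values` has no dimnames")
  }
  if (length(gene_ids) != nrow(values) || length(unit_ids) != ncol(values)) {
    stop(sprintf("dimension mismatch: %d x %d matrix vs %d gene ids and %d unit ids",
                 nrow(values), ncol(values), length(gene_ids), length(unit_ids)))
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(unit_ids)) stop("duplicate unit ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(as.character(gene_ids), as.character(unit_ids))
  integral <- all(values == round(values))
  if (is.null(norm_state)) norm_state <- if (integral) "raw_counts" else "arbitrary"
  norm_state <- match.arg(norm_state, c("raw_counts", "log_cpm", "arbitrary"))
  if (norm_state == "raw_counts" && !integral) {
    stop("norm_state 'raw_counts' requires integral values")
  }
  structure(list(values = values, norm_state = norm_state), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d units [%s]\n",
              nrow(x$values), ncol(x$values), x$norm_state))
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param em an [expression_matrix()].
#' @return character vector.
#' @export
em_genes <- function(em) rownames(em$values)

#' Unit ids of an expression matrix
#' @param em an [expression_matrix()].
#' @return character vector.
#' @export
em_units <- function(em) colnames(em$values)

#' Read an expression matrix from MatrixMarket or dense CSV
#'
#' Two layouts are supported. A MatrixMarket triplet (`.mtx`) with one-column
#' annotation files for row (gene) and column (unit) ids; or a dense CSV/TSV
#' whose header row holds unit ids and whose first column holds gene ids.
#'
#' @param matrix_path `.mtx` file or dense CSV/TSV.
#' @param genes_path,units_path one-id-per-line annotation files; required
#'   for MTX input, ignored for dense input.
#' @return an [expression_matrix()] with `norm_state` inferred
#'   (`raw_counts` if all entries are integral, else `arbitrary`).
#' @export
read_expression <- function(matrix_path, genes_path = NULL, units_path = NULL) {
  if (!file.exists(matrix_path)) stop("file not found: ", matrix_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(units_path)) {
      stop("MTX input requires genes_path and units_path annotation files")
    }
    m <- as.matrix(Matrix::readMM(matrix_path))
    genes <- readLines(genes_path)
    genes <- genes[nzchar(genes)]
    units <- readLines(units_path)
    units <- units[nzchar(units)]
    if (length(genes) != nrow(m)) {
      stop(sprintf("gene annotation has %d entries but matrix has %d rows",
                   length(genes), nrow(m)))
    }
    if (length(units) != ncol(m)) {
      stop(sprintf("unit annotation has %d entries but matrix has %d columns",
                   length(units), ncol(m)))
    }
    expression_matrix(m, genes, units)
  } else {
    sep <- if (grepl("\\.(tsv|txt)$", matrix_path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(matrix_path, header = TRUE, sep = sep, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in dense expression matrix")
    expression_matrix(m, genes, colnames(df)[-1L])
  }
}

#' Write an expression matrix as dense TSV with a provenance header
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene_id = em_genes(em), em$values, check.names = FALSE)
  write_tsv_provenance(df, path, "expression_matrix", list(norm_state = em$norm_state))
}

#' Log-CPM normalization
#'
#' Per unit, counts are divided by the unit's total, multiplied by a scale
#' factor of one million, and natural-log transformed with a pseudocount of
#' one: `value' = ln(1 + count / unit_total * 1e6)`. The pseudocount keeps
#' zeros at exactly zero and is recorded via `norm_state = "log_cpm"`.
#'
#' @param em an [expression_matrix()] with `norm_state = "raw_counts"`.
#' @return an [expression_matrix()] with `norm_state = "log_cpm"`.
#' @export
normalize_log_cpm <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$norm_state != "raw_counts") {
    stop("normalize_log_cpm requires raw counts, got norm_state '", em$norm_state, "'")
  }
  totals <- colSums(em$values)
  if (any(totals == 0)) {
    stop("unit(s) with zero total count: ",
         paste(em_units(em)[totals == 0], collapse = ", "))
  }
  v <- log1p(sweep(em$values, 2L, totals, "/") * 1e6)
  expression_matrix(v, em_genes(em), em_units(em), norm_state = "log_cpm")
}
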
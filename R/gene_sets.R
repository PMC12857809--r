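#' Construct a gene set
#'
#' @param name set name.
#' @param genes non-empty character vector of gene ids; duplicates are an
#'   error (use [read_gene_sets()] for deduplicating file input).
#' @return object of class `"gene_set"`: list with `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) stop("gene set '", name, "' has duplicated genes")
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`. The description is
#' discarded. A gene repeated on one line is dropped with a warning. Gene id
#' matching throughout the package is exact, case-sensitive string equality.
#'
#' @param path GMT file.
#' @return list of [gene_set()] objects (empty list for an empty file).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", fields[1L], "' (line ", i, ") has duplicated genes; dropped")
      genes <- unique(genes)
    }
    out[[i]] <- gene_set(fields[1L], genes)
  }
  out
}

#' Construct a ligand-receptor panel
#'
#' @param ligands,receptors equal-length character vectors; pairs must be
#'   unique and the panel non-empty.
#' @return object of class `"lr_panel"`: data.frame with columns `ligand`,
#'   `receptor`.
#' @export
lr_panel <- function(ligands, receptors) {
  stopifnot(length(ligands) == length(receptors))
  if (!length(ligands)) stop("ligand-receptor panel is empty")
  df <- data.frame(ligand = as.character(ligands),
                   receptor = as.character(receptors),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("duplicated ligand-receptor pair in panel")
  class(df) <- c("lr_panel", "data.frame")
  df
}

#' Read a ligand-receptor panel from two-column TSV
#'
#' Columns are `(ligand, receptor)`; a header row naming them is optional,
#' and `#`-comment lines are skipped.
#'
#' @param path TSV file.
#' @return an [lr_panel()].
#' @export
read_lr_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ligand-receptor panel must have two tab-separated columns")
  if (tolower(df[1L, 1L]) == "ligand") df <- df[-1L, , drop = FALSE]
  lr_panel(df[[1L]], df[[2L]])
}

#' The default four-pair recruitment panel
#'
#' Ligand-receptor pairs implicated in immune-cell recruitment from the
#' epithelium: CCL26-CCR3, CCL20-CCR6, TSLP-IL7R, IL33-IL1RL1. Shipped as
#' `inst/extdata/lr_panel_default.tsv`.
#'
#' @return an [lr_panel()] with four pairs.
#' @export
default_lr_panel <- function() {
  read_lr_panel(system.file("extdata", "lr_panel_default.tsv", package = "epimm",
                            mustWork = TRUE))
}
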
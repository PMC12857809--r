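#' Construct and validate a cell table
#'
#' A cell table holds one or more regions of interest (ROIs) worth of
#' segmented cells: planar coordinates in micrometres and a categorical
#' cell-type label (e.g. `"EPI"`, `"IMM"`, `"MLC"`). It is the input to
#' [build_proximity_graph()].
#'
#' @param df data.frame with columns `roi_id`, `cell_id`, `x`, `y`,
#'   `cell_type`. Coordinates are taken as micrometres verbatim; no origin
#'   convention is imposed and all distances downstream are Euclidean in the
#'   input frame.
#' @return the validated data.frame with class `"cell_table"`.
#' @export
cell_table <- function(df) {
  required <- c("roi_id", "cell_id", "x", "y", "cell_type")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cell table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("cell table must have at least one row")
  for (col in c("x", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric coordinate in column '", col, "' at row ",
           if (length(bad)) bad[1L] else 1L)
    }
    if (any(!is.finite(v))) {
      stop("non-finite coordinate in column '", col, "' at row ", which(!is.finite(v))[1L])
    }
  }
  df$roi_id <- as.character(df$roi_id)
  df$cell_id <- as.character(df$cell_id)
  df$cell_type <- as.character(df$cell_type)
  dup <- duplicated(df[, c("roi_id", "cell_id")])
  if (any(dup)) {
    stop("duplicated cell_id within ROI: ",
         paste(unique(df$cell_id[dup]), collapse = ", "))
  }
  df <- df[, c(required, setdiff(names(df), required)), drop = FALSE]
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Read a cell table from CSV/TSV
#'
#' @param path file path. Files ending in `.tsv`/`.txt` are read
#'   tab-separated, otherwise comma-separated. Lines starting with `#` are
#'   skipped.
#' @param column_map optional named character vector mapping the standard
#'   column names to the names used in the file, e.g.
#'   `c(x = "X_um", y = "Y_um")`.
#' @return a [cell_table()].
#' @export
read_cell_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df)) {
        stop("column_map names column '", src, "' which is not in the file")
      }
      names(df)[names(df) == src] <- std
    }
  }
  cell_table(df)
}

#' Write a cell table as TSV with a provenance header
#'
#' @param ct a [cell_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(ct, path) {
  stopifnot(inherits(ct, "cell_table"))
  write_tsv_provenance(as.data.frame(ct), path, "cell_table",
                       list(n_cells = nrow(ct), n_rois = length(unique(ct$roi_id))))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d ROI(s), types: %s\n",
              nrow(x), length(unique(x$roi_id)),
              paste(sort(unique(x$cell_type)), collapse = ", ")))
  invisible(x)
}
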
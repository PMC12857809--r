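#' Weighted ligand-receptor co-expression score for one pair
#'
#' `P = L * R / OR*`: the product of the ligand's expression in the
#' epithelial region and the receptor's expression in the immune region of
#' the same ROI, weighted by the ROI's geometric interaction odds ratio.
#' Callers must pass the corrected OR* whenever the raw one is 0, since the
#' score is undefined at OR* = 0.
#'
#' @param L ligand expression in the EPI region (>= 0).
#' @param R receptor expression in the IMM region (>= 0).
#' @param or_star geometric odds ratio for the ROI (> 0).
#' @return the weighted co-expression score `P`.
#' @export
pair_score <- function(L, R, or_star) {
  if (L < 0 || R < 0) stop("expression values must be non-negative")
  if (!is.finite(or_star) || or_star <= 0) {
    stop("or_star must be positive; pass the Haldane-Anscombe-corrected OR* ",
         "when the raw OR* is 0")
  }
  L * R / or_star
}

#' Per-ROI geometric-mean ligand-receptor interaction score
#'
#' For every ROI shared by the two region-level matrices, computes the
#' weighted co-expression score `P = L * R / OR*` for each panel pair whose
#' ligand is present in the epithelial matrix and receptor in the immune
#' matrix, then summarizes the ROI as the geometric mean
#' `score = (prod P_i)^(1/n)` over the `n` pairs used. A pair whose ligand or
#' receptor is missing is skipped with a reason and `n` adjusted; any used
#' `P = 0` makes the score exactly 0 (no pseudocount by default). Expression
#' matrices are expected at ROI level (one column per ROI); if cell-level
#' values are aggregated upstream, use the mean over cells of the named type
#' within the ROI.
#'
#' @param epi_expr,imm_expr ROI-level [expression_matrix()] objects sharing
#'   unit ids (= ROI ids).
#' @param panel an [lr_panel()].
#' @param odds named list of [compute_interaction_odds()] results (names =
#'   ROI ids), or a single `odds_result` recycled to all ROIs. The OR* used
#'   is each result's `or_star`, which is already the corrected value
#'   whenever correction was triggered.
#' @param floor non-negative value added to every `L` and `R` before scoring
#'   for callers who want strictly positive scores (default 0).
#' @return list with `summary` (data.frame `roi_id`, `n_pairs_used`,
#'   `score`; `score` is `NA` with all pairs skipped) and `pairs`
#'   (data.frame `roi_id`, `ligand`, `receptor`, `L`, `R`, `or_star`, `P`,
#'   `skipped`, `reason`).
#' @export
roi_interaction_score <- function(epi_expr, imm_expr, panel, odds, floor = 0) {
  stopifnot(inherits(epi_expr, "expr_matrix"), inherits(imm_expr, "expr_matrix"),
            inherits(panel, "lr_panel"), floor >= 0)
  rois <- intersect(em_units(epi_expr), em_units(imm_expr))
  if (!length(rois)) stop("the two matrices share no ROI ids")
  if (inherits(odds, "odds_result")) {
    odds <- stats::setNames(rep(list(odds), length(rois)), rois)
  }
  missing_or <- setdiff(rois, names(odds))
  if (length(missing_or)) {
    stop("no odds result for ROI(s): ", paste(missing_or, collapse = ", "))
  }

  pair_rows <- list()
  summ <- data.frame(roi_id = rois, n_pairs_used = 0L, score = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(rois)) {
    roi <- rois[k]
    or_star <- odds[[roi]]$or_star
    P <- numeric(0)
    for (i in seq_len(nrow(panel))) {
      lig <- panel$ligand[i]; rec <- panel$receptor[i]
      reason <- NA_character_
      L <- R <- P_i <- NA_real_
      if (!lig %in% em_genes(epi_expr)) {
        reason <- "ligand_missing_in_epi"
      } else if (!rec %in% em_genes(imm_expr)) {
        reason <- "receptor_missing_in_imm"
      } else {
        L <- epi_expr$values[lig, roi] + floor
        R <- imm_expr$values[rec, roi] + floor
        P_i <- pair_score(L, R, or_star)
        P <- c(P, P_i)
      }
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(roi_id = roi, ligand = lig, receptor = rec, L = L, R = R,
                   or_star = or_star, P = P_i, skipped = !is.na(reason),
                   reason = reason, stringsAsFactors = FALSE)
    }
    summ$n_pairs_used[k] <- length(P)
    if (length(P)) summ$score[k] <- geometric_mean(P)
  }
  list(summary = summ, pairs = do.call(rbind, pair_rows))
}
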
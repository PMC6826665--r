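#' Aggregate per-cell annotations into category percentages
#'
#' Summarizes the per-cell annotation table of one tumor and marker into
#' the percentages of spindle-shaped (SME), hypertrophic (HME) and
#' neoplastic (NME) myoepithelial cells among all marker-positive cells,
#' retaining the staining-intensity tallies for reporting. An empty
#' record set yields `n_cells = 0` with undefined (`NA`) percentages and
#' `flagged = TRUE` rather than zeros: no cells is absence of evidence,
#' not evidence of 0%.
#'
#' @param records data frame with columns `tumor_id`, `marker`,
#'   `category` (SME/HME/NME) and `intensity` (mild/moderate/marked),
#'   all rows from a single tumor and marker.
#' @return a `cell_percentages` object: list with `tumor_id`, `marker`,
#'   `pct_sme`, `pct_hme`, `pct_nme`, `n_cells`, `intensity_counts`,
#'   `flagged`.
#' @examples
#' r <- data.frame(tumor_id = "T1", marker = "calponin",
#'                 category = c("SME", "SME", "HME", "NME"),
#'                 intensity = "moderate")
#' aggregate_cell_percentages(r)
#' @export
aggregate_cell_percentages <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(structure(list(tumor_id = NA_character_, marker = NA_character_,
                          pct_sme = NA_real_, pct_hme = NA_real_,
                          pct_nme = NA_real_, n_cells = 0L,
                          intensity_counts = NULL, flagged = TRUE),
                     class = "cell_percentages"))
  }
  need <- c("tumor_id", "marker", "category", "intensity")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(records$tumor_id)) > 1 ||
      length(unique(records$marker)) > 1) {
    stop("records must all come from a single tumor and marker")
  }
  marker <- as.character(records$marker[1])
  cat <- factor(records$category, levels = c("SME", "HME", "NME"))
  if (any(is.na(cat))) stop("unknown cell category in records")
  if (marker %in% c("sma", "vimentin", "SMA") && any(cat == "NME")) {
    stop("marker '", marker, "' must not carry NME records")
  }
  counts <- table(cat)
  pct <- 100 * as.numeric(counts) / nrow(records)
  structure(list(tumor_id = as.character(records$tumor_id[1]),
                 marker = marker,
                 pct_sme = pct[1], pct_hme = pct[2], pct_nme = pct[3],
                 n_cells = nrow(records),
                 intensity_counts = table(
                   factor(records$intensity,
                          levels = c("mild", "moderate", "marked"))),
                 flagged = FALSE),
            class = "cell_percentages")
}

#' @export
print.cell_percentages <- function(x, ...) {
  if (x$flagged) {
    cat("<cell_percentages> no cells recorded (flagged)\n")
  } else {
    cat(sprintf("<cell_percentages> %s / %s (n=%d): SME %.2f%%, HME %.2f%%, NME %.2f%%\n",
                x$tumor_id, x$marker, x$n_cells,
                x$pct_sme, x$pct_hme, x$pct_nme))
  }
  invisible(x)
}

#' Classify a segmented cell as spindle-shaped or polygonal
#'
#' Deterministic morphological dichotomy on the major/minor axis ratio of
#' a segmented cell mask: cells at least `cutoff` times longer than wide
#' are spindle-shaped, all others cuboidal-to-polygonal. Cells from
#' degenerate masks (below `min_pixels`) are left unclassified (`NA`).
#'
#' @param axis_ratio numeric vector of major/minor axis ratios (>= 1).
#' @param cutoff spindle cutoff on the axis ratio (default 2.5).
#' @param area_px optional pixel counts of the cell masks.
#' @param min_pixels minimum mask size for a classifiable cell.
#' @return factor with levels `spindle`, `polygonal` (NA when
#'   unclassifiable).
#' @export
classify_cell_shape <- function(axis_ratio, cutoff = 2.5, area_px = NULL,
                                min_pixels = 5) {
  stopifnot(cutoff > 1)
  out <- ifelse(axis_ratio >= cutoff, "spindle", "polygonal")
  out[axis_ratio < 1 | is.na(axis_ratio)] <- NA
  if (!is.null(area_px)) out[area_px < min_pixels] <- NA
  factor(out, levels = c("spindle", "polygonal"))
}

#' Map an Elston-Ellis grading score to a histological grade
#'
#' Grading scores (sum of the tubule-formation, pleomorphism and mitotic
#' sub-scores) map to grades as 3-5 -> I, 6-7 -> II, 8-9 -> III.
#'
#' @param score integer vector of grading scores in `[3, 9]`.
#' @return factor with levels `I`, `II`, `III`.
#' @examples
#' grade_from_score(c(3, 5, 6, 7, 9))
#' @export
grade_from_score <- function(score) {
  if (any(is.na(score)) || any(score < 3 | score > 9) ||
      any(score != round(score))) {
    stop("grading scores must be integers in [3, 9]")
  }
  factor(ifelse(score <= 5, "I", ifelse(score <= 7, "II", "III")),
         levels = c("I", "II", "III"))
}

#' Grade distribution implied by grading-score probabilities
#'
#' Aggregates a grading-score probability table through the score-to-
#' grade mapping, giving the percentage of tumors in each grade.
#'
#' @param score_probs named probabilities over scores 3-9 (renormalized).
#' @return named numeric: percent of tumors in grades I, II, III.
#' @export
grade_distribution <- function(score_probs) {
  probs <- score_probs / sum(score_probs)
  grades <- grade_from_score(as.integer(names(probs)))
  100 * vapply(split(probs, grades), sum, numeric(1))
}
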
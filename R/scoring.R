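#' Area-based immunoreactive score (IRS)
#'
#' Weighted sum of the positive-area percentages,
#' `(W + 5*M + 10*S) / 100`, where `W`, `M`, `S` are the percentages of
#' the analyzed area with weak, moderate and strong staining. The score
#' ranges from 0 (no staining) to 10 (the whole area strongly stained)
#' and generalizes the cell-count-based immunoreactive score to area
#' measurements.
#'
#' @param weak either an [area_profile()] or the weak-area percentage.
#' @param moderate,strong positive-area percentages (ignored when an
#'   `area_profile` is supplied). All arguments are vectorized.
#' @return numeric score(s) in `[0, 10]`.
#' @examples
#' irs_area(44.86, 20.76, 15.83)
#' @export
irs_area <- function(weak, moderate = NULL, strong = NULL) {
  p <- .wms(weak, moderate, strong)
  (p$w + 5 * p$m + 10 * p$s) / 100
}

#' Area-based H-score
#'
#' Weighted sum `W + 2*M + 3*S` of the weak/moderate/strong positive-area
#' percentages; ranges from 0 to 300, generalizing the histological
#' H-score to area measurements.
#'
#' @inheritParams irs_area
#' @return numeric score(s) in `[0, 300]`.
#' @examples
#' h_score_area(44.86, 20.76, 15.83)
#' @export
h_score_area <- function(weak, moderate = NULL, strong = NULL) {
  p <- .wms(weak, moderate, strong)
  p$w + 2 * p$m + 3 * p$s
}

.wms <- function(weak, moderate, strong) {
  if (inherits(weak, "area_profile")) {
    return(list(w = weak$pct_weak, m = weak$pct_moderate,
                s = weak$pct_strong))
  }
  stopifnot(is.numeric(weak), is.numeric(moderate), is.numeric(strong))
  if (any(weak < 0 | moderate < 0 | strong < 0, na.rm = TRUE) ||
      any(weak + moderate + strong > 100 + 1e-6, na.rm = TRUE)) {
    stop("positive-area percentages must be nonnegative and sum to <= 100")
  }
  list(w = weak, m = moderate, s = strong)
}

#' Summarize the representative fields of one tumor and marker
#'
#' Averages 1-3 per-field [area_profile()]s class-wise and computes the
#' area-based scores on the mean profile. Both scores are linear in the
#' class percentages, so the score of the mean profile equals the mean of
#' the per-field scores; the two conventions coincide.
#'
#' @param profiles list of `area_profile`s (1 to 3, one per field).
#' @param tumor_id,marker identifiers carried into the summary.
#' @return a `marker_area_summary`: list with `tumor_id`, `marker`,
#'   `n_fields`, the mean `profile`, and `irs_area` / `h_score_area`.
#' @export
summarize_marker <- function(profiles, tumor_id = NA_character_,
                             marker = NA_character_) {
  if (length(profiles) == 0) stop("no profiles to summarize")
  if (length(profiles) > 3) stop("at most three fields per tumor and marker")
  stopifnot(all(vapply(profiles, inherits, logical(1), "area_profile")))
  w <- mean(vapply(profiles, `[[`, numeric(1), "pct_weak"))
  m <- mean(vapply(profiles, `[[`, numeric(1), "pct_moderate"))
  s <- mean(vapply(profiles, `[[`, numeric(1), "pct_strong"))
  mean_profile <- area_profile(w, m, s)
  structure(list(tumor_id = tumor_id, marker = marker,
                 n_fields = length(profiles),
                 profile = mean_profile,
                 irs_area = irs_area(mean_profile),
                 h_score_area = h_score_area(mean_profile)),
            class = "marker_area_summary")
}

#' @export
print.marker_area_summary <- function(x, ...) {
  cat(sprintf(
    "<marker_area_summary> %s / %s over %d field(s): positive %.2f%%, IRS %.3f, H-score %.2f\n",
    x$tumor_id, x$marker, x$n_fields, x$profile$pct_total_positive,
    x$irs_area, x$h_score_area))
  invisible(x)
}
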
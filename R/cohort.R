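#' Parameters for the synthetic tumor cohort generator
#'
#' Bundles every knob of [generate_cohort()] with defaults that emulate a
#' published case series of 119 pet-rabbit mammary carcinomas: age of the
#' animals (truncated normal, 22 of 119 missing), sex (79% female vs 21%
#' female-spayed, 12 missing), percentage of tumor area with tubular growth,
#' mitotic count per 10 high-power fields, Elston-Ellis grading score, the
#' per-marker immunopositive-area marginals, and the percentages of
#' spindle-shaped (SME), hypertrophic (HME) and neoplastic (NME)
#' myoepithelial cells among marker-positive cells.
#'
#' Rank correlations between cohort variables are planted through a
#' Gaussian copula: named Spearman targets in `planted_rho` are converted
#' to latent Pearson correlations via `r = 2*sin(pi*rho/6)` (exact for the
#' bivariate normal) and imposed on latent normal scores before the
#' marginal back-transforms, which are all monotone and therefore preserve
#' the ranks.
#'
#' @param n_tumors cohort size.
#' @param age_mean,age_sd,age_range mean, SD (years) and truncation range of
#'   the age distribution.
#' @param age_missing number of tumors with unknown age (missing completely
#'   at random).
#' @param sex_female_frac proportion of intact females among tumors with a
#'   known sex; the remainder are female-spayed (`fs`).
#' @param sex_missing number of tumors with unknown sex.
#' @param tubular_range range (percent of tumor area) of tubular growth.
#' @param tubular_shapes beta shape parameters of the scaled tubular-growth
#'   distribution (interior mode).
#' @param mitoses_range admissible range of the mitotic count per 10 HPFs.
#' @param mitoses_size,mitoses_mu negative-binomial parameters of the
#'   (range-truncated) mitotic-count distribution.
#' @param grading_score_probs named probabilities for grading scores 3-8;
#'   renormalized (with a warning) if they do not sum to 1.
#' @param nme_mean,nme_sd,nme_range moments and range of the percentage of
#'   neoplastic myoepithelial (calponin-positive tumor) cells among
#'   calponin-positive cells, for tumors that have any.
#' @param nme_zero_count number of tumors with no NME at all.
#' @param hme_absent_count number of tumors whose myoepithelial cells are
#'   solely spindle-shaped (no HME, for every marker).
#' @param area_excluded_count tumors flagged ineligible for area
#'   measurement (e.g. unspecific staining of secretory material).
#' @param planted_rho named numeric vector of Spearman targets; recognized
#'   names are `nme_tubular`, `nme_mitoses`, `nme_grading`, `hme_age`,
#'   `sme_age`, `age_tubular`, `age_mitoses`, `age_grading`,
#'   `tubular_mitoses`, `tubular_grading`, `mitoses_grading`.
#' @param marker_areas per-marker list of `range` and `median` of the total
#'   immunopositive area (percent of analyzed area).
#' @param marker_hme per-marker list of `range` and `median` of the HME
#'   percentage among positive cells (SME is the complement, minus NME for
#'   calponin).
#' @param intensity_alpha Dirichlet concentration of the weak/moderate/
#'   strong split of the positive area.
#' @param marker_area_cor latent correlation between the positive areas of
#'   different markers (shared tumor-level factor).
#' @param seed default RNG seed used by [generate_cohort()].
#' @return an object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_tumors = 119,
                          age_mean = 5.3,
                          age_sd = 1.59,
                          age_range = c(1.5, 10),
                          age_missing = 22,
                          sex_female_frac = 0.79,
                          sex_missing = 12,
                          tubular_range = c(5, 90),
                          tubular_shapes = c(1.8, 2.2),
                          mitoses_range = c(0L, 32L),
                          mitoses_size = 1.6,
                          mitoses_mu = 7,
                          grading_score_probs = c(`3` = 2, `4` = 13, `5` = 42,
                                                  `6` = 21, `7` = 21,
                                                  `8` = 2) / 101,
                          nme_mean = 8,
                          nme_sd = 4.59,
                          nme_range = c(1.62, 22),
                          nme_zero_count = 8,
                          hme_absent_count = 4,
                          area_excluded_count = 9,
                          planted_rho = c(nme_tubular = 0.214,
                                          nme_mitoses = -0.147,
                                          nme_grading = -0.157,
                                          hme_age = 0.139),
                          marker_areas = list(
                            ck       = list(range = c(13.75, 100),  median = 78.09),
                            calponin = list(range = c(5.55, 87.62), median = 52.53),
                            vimentin = list(range = c(2.80, 84.18), median = 47.95),
                            sma      = list(range = c(1.31, 88.82), median = 45.08)),
                          marker_hme = list(
                            sma      = list(range = c(0, 79.36), median = 32.83),
                            vimentin = list(range = c(0, 80.15), median = 32.59),
                            calponin = list(range = c(0, 70.90), median = 39.01)),
                          intensity_alpha = c(weak = 9.3, moderate = 5.0,
                                              strong = 0.75),
                          marker_area_cor = 0.5,
                          seed = 1L) {
  p <- as.list(environment())

  stopifnot(n_tumors >= 1,
            length(age_range) == 2, age_range[1] < age_range[2],
            length(tubular_range) == 2, tubular_range[1] < tubular_range[2],
            length(mitoses_range) == 2, mitoses_range[1] < mitoses_range[2],
            length(nme_range) == 2, nme_range[1] < nme_range[2])
  if (sex_female_frac < 0 || sex_female_frac > 1) {
    stop("sex_female_frac must be a proportion in [0, 1]")
  }
  counts <- c(age_missing = age_missing, sex_missing = sex_missing,
              nme_zero_count = nme_zero_count,
              hme_absent_count = hme_absent_count,
              area_excluded_count = area_excluded_count)
  bad <- counts < 0 | counts > n_tumors
  if (any(bad)) {
    stop("counts must lie in [0, n_tumors]: ",
         paste(names(counts)[bad], collapse = ", "))
  }
  s <- sum(grading_score_probs)
  if (any(grading_score_probs < 0)) stop("grading_score_probs must be >= 0")
  if (abs(s - 1) > 1e-9) {
    warning(sprintf("grading_score_probs sum to %.4f; renormalizing", s))
    p$grading_score_probs <- grading_score_probs / s
  }
  if (marker_area_cor < 0 || marker_area_cor >= 1) {
    stop("marker_area_cor must be in [0, 1)")
  }
  # planted pairs must name known latent variables and assemble into a
  # positive semi-definite latent correlation matrix
  p$latent_sigma <- plant_latent_sigma(p$planted_rho)
  structure(p, class = "cohort_params")
}

# latent variables of the copula, in draw order
.latent_vars <- c("age", "tubular", "mitoses", "grading", "hme", "nme")

# Translate named Spearman targets into a latent Pearson correlation
# matrix; rejects unknown pair names and infeasible (non-PSD) matrices,
# naming the most implicated pair.
plant_latent_sigma <- function(planted_rho) {
  sigma <- diag(length(.latent_vars))
  dimnames(sigma) <- list(.latent_vars, .latent_vars)
  if (length(planted_rho) == 0) return(sigma)
  if (is.null(names(planted_rho)) || any(names(planted_rho) == "")) {
    stop("planted_rho must be a named vector of '<var1>_<var2>' pairs")
  }
  for (nm in names(planted_rho)) {
    pair <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% .latent_vars)) {
      stop("unknown planted_rho pair '", nm, "'; variables must be two of: ",
           paste(.latent_vars, collapse = ", "))
    }
    rho <- planted_rho[[nm]]
    if (abs(rho) > 1) stop("planted_rho['", nm, "'] outside [-1, 1]")
    r <- 2 * sin(pi * rho / 6)  # Spearman -> latent Pearson
    sigma[pair[1], pair[2]] <- r
    sigma[pair[2], pair[1]] <- r
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    worst <- names(planted_rho)[which.max(abs(planted_rho))]
    stop("planted correlation matrix is not positive semi-definite ",
         sprintf("(min eigenvalue %.3g); ", min(ev)),
         "the largest requested correlation involves pair '", worst, "'")
  }
  sigma
}

#' Generate a synthetic tumor cohort
#'
#' Draws a cohort table with one row per tumor: signalment (age, sex),
#' histology (tubular growth percentage, mitotic count, grading score and
#' grade), area-measurement eligibility, per-marker immunopositive-area
#' profiles with the derived area-based IRS and H-score, and per-marker
#' myoepithelial cell percentages. Rank correlations named in
#' `params$planted_rho` are induced by a Gaussian copula; structural
#' counts (tumors with no NME, tumors with solely spindle-shaped
#' myoepithelial cells, area-ineligible tumors) and the sex/missingness
#' counts are realized exactly.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer RNG seed; defaults to `params$seed`. Identical
#'   `(params, seed)` give bit-identical cohorts.
#' @return a `data.frame` with `params$n_tumors` rows; columns documented
#'   in the package vignette. Markers are `ck`, `sma`, `vimentin`,
#'   `calponin`; per-marker columns follow the pattern
#'   `<marker>_area_total`, `<marker>_area_weak`, `<marker>_area_moderate`,
#'   `<marker>_area_strong`, `<marker>_irs`, `<marker>_hscore`, and (for
#'   the myoepithelial markers) `<marker>_pct_sme`, `<marker>_pct_hme`,
#'   `<marker>_pct_nme`.
#' @examples
#' coh <- generate_cohort(cohort_params(), seed = 1)
#' range(coh$tubular_growth)
#' @export
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  n <- params$n_tumors

  # --- latent normal scores with the planted correlation structure ------
  z <- matrix(stats::rnorm(n * length(.latent_vars)), nrow = n)
  z <- z %*% chol_psd(params$latent_sigma)
  colnames(z) <- .latent_vars
  u <- stats::pnorm(z)  # uniform scores, rank-preserving

  # --- marginal back-transforms (all monotone in the latent score) ------
  age <- qtruncnorm(u[, "age"], params$age_mean, params$age_sd,
                    params$age_range[1], params$age_range[2])

  tb <- params$tubular_shapes
  tubular <- params$tubular_range[1] +
    diff(params$tubular_range) * stats::qbeta(u[, "tubular"], tb[1], tb[2])

  # negative binomial truncated to the admissible mitotic-count range
  lo <- params$mitoses_range[1]; hi <- params$mitoses_range[2]
  p_lo <- if (lo > 0) stats::pnbinom(lo - 1, size = params$mitoses_size,
                                     mu = params$mitoses_mu) else 0
  p_hi <- stats::pnbinom(hi, size = params$mitoses_size, mu = params$mitoses_mu)
  mitoses <- stats::qnbinom(p_lo + u[, "mitoses"] * (p_hi - p_lo),
                            size = params$mitoses_size, mu = params$mitoses_mu)

  probs <- params$grading_score_probs
  scores <- as.integer(names(probs))
  grading <- scores[findInterval(u[, "grading"], cumsum(probs),
                                 left.open = TRUE) + 1L]
  grading <- pmin(grading, max(scores))

  # --- myoepithelial cell percentages -----------------------------------
  # HME share among positive cells; the `hme_absent_count` lowest latent
  # scores become structural zeros (solely spindle-shaped tumors), shared
  # across markers through the common latent.
  hme_zero <- rank(z[, "hme"], ties.method = "first") <= params$hme_absent_count
  hme <- list()
  for (m in names(params$marker_hme)) {
    mg <- params$marker_hme[[m]]
    sh <- beta_shapes_from_median(mg$range[1], mg$range[2], mg$median)
    x <- mg$range[1] + diff(mg$range) * stats::qbeta(u[, "hme"], sh[1], sh[2])
    x[hme_zero] <- 0
    hme[[m]] <- x
  }

  # NME (calponin-positive tumor cells) with structural zeros at the
  # lowest latent scores
  nme_zero <- rank(z[, "nme"], ties.method = "first") <= params$nme_zero_count
  nsh <- beta_shapes_from_moments(params$nme_range[1], params$nme_range[2],
                                  params$nme_mean, params$nme_sd)
  nme <- params$nme_range[1] +
    diff(params$nme_range) * stats::qbeta(u[, "nme"], nsh[1], nsh[2])
  nme[nme_zero] <- 0

  # calponin percentages must sum to 100; rescale HME if a tumor's
  # HME + NME would exceed the total (rare joint extreme)
  cal_hme <- hme[["calponin"]]
  over <- cal_hme + nme > 99.9
  cal_hme[over] <- pmax(0, 99.9 - nme[over])
  hme[["calponin"]] <- cal_hme

  # --- immunopositive areas and scores ----------------------------------
  w <- params$marker_area_cor
  z_shared <- stats::rnorm(n)
  alpha <- params$intensity_alpha
  areas <- list()
  for (m in names(params$marker_areas)) {
    mg <- params$marker_areas[[m]]
    zi <- sqrt(w) * z_shared + sqrt(1 - w) * stats::rnorm(n)
    sh <- beta_shapes_from_median(mg$range[1], mg$range[2], mg$median)
    total <- mg$range[1] +
      diff(mg$range) * stats::qbeta(stats::pnorm(zi), sh[1], sh[2])
    shares <- rdirichlet(n, alpha)
    areas[[m]] <- data.frame(total = total,
                             weak = total * shares[, 1],
                             moderate = total * shares[, 2],
                             strong = total * shares[, 3])
  }

  # --- exact-count categorical assignments ------------------------------
  sex <- rep(NA_character_, n)
  known <- sample.int(n, n - params$sex_missing)
  n_f <- round(params$sex_female_frac * length(known))
  sex[known] <- "fs"
  sex[sample(known, n_f)] <- "f"

  age[sample.int(n, params$age_missing)] <- NA_real_

  area_eligible <- rep(TRUE, n)
  area_eligible[sample.int(n, params$area_excluded_count)] <- FALSE

  # --- assemble ----------------------------------------------------------
  coh <- data.frame(
    tumor_id = sprintf("T%03d", seq_len(n)),
    age = age,
    age_cat = factor(ifelse(is.na(age), NA,
                            ifelse(age <= 5, "le5", "gt5")),
                     levels = c("le5", "gt5")),
    sex = factor(sex, levels = c("f", "fs")),
    tubular_growth = tubular,
    mitotic_count = as.integer(mitoses),
    grading_score = grading,
    grade = grade_from_score(grading),
    area_eligible = area_eligible,
    stringsAsFactors = FALSE
  )
  for (m in names(areas)) {
    a <- areas[[m]]
    coh[[paste0(m, "_area_total")]] <- a$total
    coh[[paste0(m, "_area_weak")]] <- a$weak
    coh[[paste0(m, "_area_moderate")]] <- a$moderate
    coh[[paste0(m, "_area_strong")]] <- a$strong
    coh[[paste0(m, "_irs")]] <- irs_area(a$weak, a$moderate, a$strong)
    coh[[paste0(m, "_hscore")]] <- h_score_area(a$weak, a$moderate, a$strong)
  }
  for (m in names(hme)) {
    pct_nme <- if (m == "calponin") nme else rep(0, n)
    coh[[paste0(m, "_pct_sme")]] <- 100 - hme[[m]] - pct_nme
    coh[[paste0(m, "_pct_hme")]] <- hme[[m]]
    coh[[paste0(m, "_pct_nme")]] <- pct_nme
  }
  attr(coh, "params") <- params
  attr(coh, "seed") <- as.integer(seed)
  coh
}

# Cholesky factor tolerant of a semi-definite matrix (falls back to an
# eigen square root when a planted matrix is singular but valid).
chol_psd <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(sigma, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sigma)) %*% t(e$vectors))
}

# Quantile transform of a uniform score to a truncated normal.
qtruncnorm <- function(u, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}
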
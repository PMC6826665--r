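#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected (average-rank) Spearman coefficient on pairwise-complete
#' observations, with the two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value
#'   are dropped.
#' @return list with `rho`, `p`, `n`, and `flagged` (`TRUE` when the
#'   coefficient is undefined because a vector is constant after
#'   filtering).
#' @examples
#' spearman_rank(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, flagged = FALSE)
}

#' Simple linear model with ANOVA model comparison
#'
#' Ordinary least squares of `response ~ predictor` on complete cases,
#' with the p-value from the F test comparing the fitted model against
#' the intercept-only model (single-stratum analysis of variance). The
#' predictor may be numeric or a two-level category, in which case the
#' reported estimate is the group contrast and the F test is equivalent
#' to the equal-variance two-sample t-test.
#'
#' @param data data frame holding both variables.
#' @param response,predictor column names.
#' @param alpha significance level for the `significant` flag.
#' @return one-row data frame (a `StatResult` row): `parameter_1`
#'   (predictor), `parameter_2` (response), `n`, `test`, `estimate`
#'   (slope or contrast), `p_value`, `rho` (`NA`; filled by
#'   [run_battery()] for Spearman rows), `significant`.
#' @export
fit_linear <- function(data, response, predictor, alpha = 0.05) {
  stopifnot(is.data.frame(data),
            response %in% names(data), predictor %in% names(data))
  d <- data[stats::complete.cases(data[[response]], data[[predictor]]),
            c(response, predictor)]
  n <- nrow(d)
  if (n < 3) stop("need at least 3 complete cases for '", predictor,
                  "' vs '", response, "'")
  x <- d[[predictor]]
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) {
    x <- droplevels(x)
    if (nlevels(x) != 2) {
      stop("categorical predictor '", predictor,
           "' must have exactly two observed levels (got ", nlevels(x), ")")
    }
    d[[predictor]] <- x
  } else if (stats::sd(x) == 0) {
    stop("rank-deficient design: predictor '", predictor, "' is constant")
  }
  f1 <- stats::as.formula(paste(response, "~", predictor))
  fit1 <- stats::lm(f1, data = d)
  fit0 <- stats::lm(stats::as.formula(paste(response, "~ 1")), data = d)
  an <- stats::anova(fit0, fit1)
  p <- an[["Pr(>F)"]][2]
  if (is.na(p)) {
    # anova() leaves Pr(>F) empty when the model SS underflows to ~0;
    # recompute from the summary F statistic (p -> 1 for a null fit)
    f <- summary(fit1)$fstatistic
    p <- if (is.null(f)) NA_real_ else
      unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  }
  data.frame(parameter_1 = predictor,
             parameter_2 = response,
             n = n,
             test = "lm+ANOVA",
             estimate = unname(stats::coef(fit1)[2]),
             p_value = p,
             rho = NA_real_,
             rho_p = NA_real_,
             significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Default battery specification
#'
#' The default set of cohort analyses: each signalment/histology variable
#' (age, age category at 5 years, sex, tubular growth, mitotic count,
#' grading score) against the calponin SME, HME and NME percentages. Each
#' cell-percentage response is analyzed over the tumors in which the
#' category exists: SME over all tumors, HME over tumors with any
#' hypertrophic cells, NME over tumors with any calponin-positive tumor
#' cells — which is how the per-row case counts of the motivating study
#' arise. Spearman correlations are computed for every numeric predictor.
#'
#' @return data frame with columns `predictor`, `response`, `subset`,
#'   `spearman`.
#' @export
default_battery_spec <- function() {
  predictors <- c("age", "age_cat", "sex", "tubular_growth",
                  "mitotic_count", "grading_score")
  responses <- c(calponin_pct_sme = "all",
                 calponin_pct_hme = "hme_positive",
                 calponin_pct_nme = "nme_positive")
  spec <- expand.grid(response = names(responses),
                      predictor = predictors,
                      stringsAsFactors = FALSE)[, c("predictor", "response")]
  spec$subset <- responses[spec$response]
  spec$spearman <- !(spec$predictor %in% c("age_cat", "sex"))
  rownames(spec) <- NULL
  spec
}

.battery_subset <- function(cohort, subset) {
  switch(subset,
         all = cohort,
         hme_positive = cohort[cohort$calponin_pct_hme > 0, ],
         nme_positive = cohort[cohort$calponin_pct_nme > 0, ],
         stop("unknown battery subset '", subset, "'"))
}

#' Run the cohort statistics battery
#'
#' Executes every configured predictor/response pair: a simple linear
#' model with ANOVA model comparison always, and a tie-corrected Spearman
#' rank correlation for numeric predictors. Cases are pairwise-complete
#' per analysis and the per-row `n` reports the cases actually used.
#' The battery is deterministic given a cohort.
#'
#' @param cohort a cohort data frame (see [generate_cohort()]).
#' @param spec battery specification, as from [default_battery_spec()].
#' @param alpha significance level (two-sided convention throughout).
#' @return data frame of `StatResult` rows; for Spearman rows, `rho` and
#'   `rho_p` are filled and `test` is `"lm+ANOVA, Spearman"`.
#' @examples
#' coh <- generate_cohort(cohort_params(), seed = 1)
#' head(run_battery(coh))
#' @export
run_battery <- function(cohort, spec = default_battery_spec(),
                        alpha = 0.05) {
  stopifnot(is.data.frame(cohort), is.data.frame(spec),
            all(c("predictor", "response", "subset", "spearman")
                %in% names(spec)))
  miss <- setdiff(unique(c(spec$predictor, spec$response)), names(cohort))
  if (length(miss)) {
    stop("battery spec names variables absent from the cohort: ",
         paste(miss, collapse = ", "))
  }
  rows <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    d <- .battery_subset(cohort, spec$subset[i])
    res <- fit_linear(d, spec$response[i], spec$predictor[i], alpha = alpha)
    if (isTRUE(spec$spearman[i])) {
      sp <- spearman_rank(d[[spec$predictor[i]]], d[[spec$response[i]]])
      res$rho <- sp$rho
      res$rho_p <- sp$p
      res$test <- "lm+ANOVA, Spearman"
    }
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare immunopositive areas and scores across markers
#'
#' Contrasts the cytokeratin (CK) readout against each myoepithelial
#' marker on the total positive area, the area-based IRS and the
#' area-based H-score, through the linear-model pathway of
#' [fit_linear()] on the area-eligible tumors; per-marker medians are
#' reported alongside. A marker absent from the cohort is skipped with a
#' message.
#'
#' @param cohort cohort data frame with `<marker>_area_total`,
#'   `<marker>_irs`, `<marker>_hscore` columns and an `area_eligible`
#'   flag.
#' @param reference reference marker (default `"ck"`).
#' @param markers markers contrasted against the reference.
#' @return list with `contrasts` (StatResult rows; `parameter_1` is the
#'   comparison, `parameter_2` the measure) and `medians` (marker x
#'   measure table of medians over eligible tumors).
#' @export
compare_marker_areas <- function(cohort, reference = "ck",
                                 markers = c("sma", "vimentin", "calponin")) {
  stopifnot(is.data.frame(cohort))
  elig <- if ("area_eligible" %in% names(cohort)) {
    cohort[cohort$area_eligible, ]
  } else cohort
  measures <- c(area_total = "_area_total", irs = "_irs", hscore = "_hscore")

  have <- function(m) all(paste0(m, measures) %in% names(cohort))
  if (!have(reference)) stop("reference marker '", reference,
                             "' has no area columns in the cohort")
  markers <- Filter(function(m) {
    ok <- have(m)
    if (!ok) message("marker '", m, "' absent from cohort; contrast skipped")
    ok
  }, markers)

  rows <- list()
  for (m in markers) {
    for (meas in names(measures)) {
      ref_col <- paste0(reference, measures[[meas]])
      m_col <- paste0(m, measures[[meas]])
      stacked <- data.frame(
        value = c(elig[[ref_col]], elig[[m_col]]),
        marker = factor(rep(c(reference, m), each = nrow(elig)),
                        levels = c(m, reference)))
      res <- fit_linear(stacked, "value", "marker")
      res$parameter_1 <- paste(reference, "vs", m)
      res$parameter_2 <- meas
      rows[[paste(m, meas)]] <- res
    }
  }
  med <- sapply(names(measures), function(meas) {
    vapply(c(reference, markers), function(m) {
      stats::median(elig[[paste0(m, measures[[meas]])]], na.rm = TRUE)
    }, numeric(1))
  })
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL
  list(contrasts = contrasts, medians = as.data.frame(med))
}

#' Cohort summary counts and percentages
#'
#' Reports the cohort's headline descriptive statistics, each rounded
#' half-up to the precision conventionally printed: percentage of tumors
#' with any calponin-positive tumor cells (NME, 0 dp), with both
#' myoepithelial morphologies and with solely spindle-shaped
#' myoepithelial cells (1 dp), sex percentages among tumors with a known
#' sex (0 dp), age mean (1 dp) and SD (2 dp) over known ages, the grade
#' distribution (0 dp), and the observed tubular-growth and
#' mitotic-count ranges.
#'
#' @param cohort cohort data frame.
#' @return named list of summary values.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  n <- nrow(cohort)
  nme_pos <- sum(cohort$calponin_pct_nme > 0)
  hme_pos <- sum(cohort$calponin_pct_hme > 0)
  sex_known <- cohort$sex[!is.na(cohort$sex)]
  age_known <- cohort$age[!is.na(cohort$age)]
  grades <- table(cohort$grade)
  list(
    n_tumors = n,
    n_nme_positive = nme_pos,
    pct_nme_positive = round_half_up(100 * nme_pos / n, 0),
    n_both_shapes = hme_pos,
    pct_both_shapes = round_half_up(100 * hme_pos / n, 1),
    n_solely_spindle = n - hme_pos,
    pct_solely_spindle = round_half_up(100 * (n - hme_pos) / n, 1),
    n_sex_known = length(sex_known),
    pct_female = round_half_up(100 * mean(sex_known == "f"), 0),
    pct_female_spayed = round_half_up(100 * mean(sex_known == "fs"), 0),
    n_age_known = length(age_known),
    age_mean = round_half_up(mean(age_known), 1),
    age_sd = round_half_up(stats::sd(age_known), 2),
    pct_grade = round_half_up(100 * as.numeric(grades) / n, 0),
    tubular_range = range(cohort$tubular_growth),
    mitoses_range = range(cohort$mitotic_count),
    n_area_eligible = sum(cohort$area_eligible)
  )
}
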
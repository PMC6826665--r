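test_that("spearman handles the perfect monotone cases", {
  expect_equal(spearman_rank(1:3, 1:3)$rho, 1)
  expect_equal(spearman_rank(1:3, 3:1)$rho, -1)
  expect_equal(spearman_rank(1:3, 1:3)$p, 0)
})

test_that("spearman equals the ranks-then-Pearson oracle including ties", {
  expect_equal(spearman_rank(c(1, 2, 2, 4), c(1, 3, 2, 4))$rho,
               oracle_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)   # heavy ties
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rank(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman filters incomplete pairs and flags constants", {
  res <- spearman_rank(c(1, 2, NA, 4, 5), c(2, 1, 3, NA, 5))
  expect_equal(res$n, 3)
  const <- spearman_rank(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(const$flagged)
  expect_true(is.na(const$rho))
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})

test_that("a noiseless linear relation is fit exactly", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  res <- fit_linear(d, "y", "x")
  expect_equal(res$estimate, 2, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-12)
  expect_true(res$significant)
})

test_that("two-level F test equals the pooled two-sample t test", {
  set.seed(11)
  for (i in 1:10) {
    d <- data.frame(g = rep(c("a", "b"), each = 12),
                    y = rnorm(24, mean = rep(c(0, 0.5), each = 12)))
    res <- fit_linear(d, "y", "g")
    tt <- t.test(y ~ g, data = d, var.equal = TRUE)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("null contrasts and degenerate designs behave correctly", {
  d <- data.frame(g = rep(c("a", "b"), each = 5), y = rep(1:5, 2))
  res <- fit_linear(d, "y", "g")
  expect_gt(res$p_value, 0.99)

  expect_error(fit_linear(data.frame(x = rep(1, 5), y = 1:5), "y", "x"),
               "rank-deficient")
  expect_error(
    fit_linear(data.frame(g = rep("a", 5), y = 1:5), "y", "g"),
    "two observed levels")
})

test_that("linear-model type-I error is calibrated under the null", {
  set.seed(29)
  n <- 119
  p <- replicate(1000, {
    fit_linear(data.frame(x = rnorm(n), y = rnorm(n)), "y", "x")$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("the battery reports pairwise-complete case counts per subset", {
  coh <- generate_cohort(cohort_params(), seed = 5)
  bat <- run_battery(coh)
  expect_equal(nrow(bat), 18)
  pick <- function(p1, p2) bat$n[bat$parameter_1 == p1 & bat$parameter_2 == p2]
  # age known for 97; structural subsets 119 / 115 / 111
  expect_equal(pick("age", "calponin_pct_sme"), 97)
  expect_equal(pick("tubular_growth", "calponin_pct_sme"), 119)
  expect_equal(pick("tubular_growth", "calponin_pct_hme"), 115)
  expect_equal(pick("tubular_growth", "calponin_pct_nme"), 111)
  expect_equal(pick("sex", "calponin_pct_sme"), 107)
  # Spearman columns filled exactly for the numeric predictors
  expect_true(all(is.na(bat$rho[bat$parameter_1 %in% c("age_cat", "sex")])))
  expect_true(all(!is.na(bat$rho[bat$parameter_1 == "tubular_growth"])))
})

test_that("the battery is deterministic and rejects unknown variables", {
  coh <- generate_cohort(cohort_params(), seed = 5)
  expect_identical(run_battery(coh), run_battery(coh))
  bad <- default_battery_spec()
  bad$predictor[1] <- "no_such_column"
  expect_error(run_battery(coh, bad), "absent from the cohort")
})

test_that("under a global null no association is flagged beyond chance", {
  p <- cohort_params(planted_rho = numeric(0))
  hits <- vapply(1:25, function(s) {
    bat <- run_battery(generate_cohort(p, seed = 1000 + s))
    mean(bat$significant)
  }, numeric(1))
  # 18 tests at alpha = 0.05: average flag rate should sit near 0.05
  expect_lt(mean(hits), 0.12)
})

test_that("marker comparisons flag the planted CK dominance and report medians", {
  coh <- generate_cohort(cohort_params(), seed = 21)
  cmp <- compare_marker_areas(coh)
  expect_equal(nrow(cmp$contrasts), 9)
  area_rows <- cmp$contrasts[cmp$contrasts$parameter_2 == "area_total", ]
  expect_true(all(area_rows$significant))
  expect_true(all(cmp$medians["ck", ] > cmp$medians["sma", ]))
  # a marker without columns is skipped with a message
  expect_message(
    cmp2 <- compare_marker_areas(coh, markers = c("sma", "p63")),
    "contrast skipped")
  expect_equal(nrow(cmp2$contrasts), 3)
})

test_that("cohort summary reproduces the printed count ratios", {
  coh <- generate_cohort(cohort_params(), seed = 2)
  s <- cohort_summary(coh)
  expect_equal(s$pct_nme_positive, 93)
  expect_equal(s$pct_both_shapes, 96.6)
  expect_equal(s$pct_solely_spindle, 3.4)
  expect_equal(s$pct_female, 79)
  expect_equal(s$pct_female_spayed, 21)
  expect_equal(s$n_age_known, 97)
  expect_equal(s$n_area_eligible, 110)
})

test_that("round half up matches printed-precision conventions", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(96.639, 1), 96.6)
  expect_equal(round_half_up(79.44), 79)
})
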
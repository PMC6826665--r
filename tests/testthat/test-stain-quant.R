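test_that("optical density and stain separation invert the forward model", {
  v <- hdab_stain_vectors()
  # pure white pixel carries no DAB
  white <- ihc_tile(array(255, c(2, 2, 3)))
  expect_equal(separate_stains(white)[1, 1], 0)
  # pure DAB pixel at a known density is recovered closely
  for (d in c(0.2, 0.6, 1.0)) {
    px <- round(255 * 10^(-(d * v[, "dab"])))
    tile <- ihc_tile(array(rep(px, each = 4), c(2, 2, 3)))
    expect_lt(abs(separate_stains(tile)[1, 1] - d), 0.02)
  }
  # pure hematoxylin projects to (clamped) zero DAB, below any threshold
  px <- round(255 * 10^(-(0.7 * v[, "hematoxylin"])))
  tile <- ihc_tile(array(rep(px, each = 4), c(2, 2, 3)))
  expect_lt(separate_stains(tile)[1, 1], intensity_thresholds()[1])
})

test_that("degenerate stain vectors are rejected", {
  bad <- hdab_stain_vectors()
  bad[, 2] <- bad[, 1]
  expect_error(separate_stains(ihc_tile(array(128, c(2, 2, 3))), bad),
               "collinear")
  expect_error(hdab_stain_vectors(dab = c(0.650, 0.704, 0.286)), "collinear")
})

test_that("pixel classification uses half-open intervals with upper class at ties", {
  th <- intensity_thresholds()
  od <- matrix(c(0, 0.149, 0.15, 0.40, 0.79, 0.80, 2), 1)
  lab <- classify_pixels(od, th)
  expect_equal(as.character(lab),
               c("negative", "negative", "weak", "moderate", "moderate",
                 "strong", "strong"))
  expect_error(classify_pixels(od, th, mask = matrix(FALSE, 1, 7)),
               "empty analysis mask")
  expect_error(intensity_thresholds(0.4, 0.2, 0.8), "thresholds must")
})

test_that("area quantification is exact counting over the analyzed mask", {
  lab <- matrix(factor(rep(c("negative", "weak", "moderate", "strong"),
                           c(40, 30, 20, 10)),
                       levels = c("negative", "weak", "moderate", "strong")),
                10, 10)
  prof <- quantify_areas(lab)
  expect_equal(profile_vec(prof), c(40, 30, 20, 10))
  expect_equal(prof$pct_total_positive, 60)

  all_neg <- matrix(factor("negative",
                           levels = c("negative", "weak", "moderate",
                                      "strong")), 5, 5)
  prof0 <- quantify_areas(all_neg)
  expect_equal(profile_vec(prof0), c(100, 0, 0, 0))
  expect_equal(prof0$pct_total_positive, 0)
})

test_that("area percentages always sum to 100 and ignore pixel order", {
  for (s in 1:5) {
    tg <- generate_tile(tile_spec(width = 40, height = 40), seed = s)
    od <- separate_stains(correct_illumination(tg$tile))
    prof <- quantify_areas(classify_pixels(od))
    expect_equal(prof$pct_negative + prof$pct_total_positive, 100,
                 tolerance = 1e-9)
    # permuting pixel positions leaves the profile unchanged
    set.seed(s)
    perm <- matrix(sample(od), nrow(od))
    expect_equal(unclass(quantify_areas(classify_pixels(perm))),
                 unclass(prof))
  }
})

test_that("quantification matches ground truth exactly on clean tiles", {
  sp <- tile_spec(width = 80, height = 80,
                  class_fractions = c(negative = 0.4, weak = 0.3,
                                      moderate = 0.2, strong = 0.1),
                  gradient_amplitude = 0, noise_sd = 0)
  for (s in 1:4) {
    tg <- generate_tile(sp, seed = s)
    prof <- quantify_tile(tg$tile, correct = FALSE)
    expect_equal(profile_vec(prof), unname(tg$truth$fractions))
    # labels agree with ground truth pixel by pixel
    od <- separate_stains(tg$tile)
    lab <- classify_pixels(od)
    expect_gte(mean(as.character(lab) == as.character(tg$truth$labels)), 0.99)
  }
})

test_that("illumination correction recovers the area profile under a gradient", {
  sp <- tile_spec(width = 96, height = 96, gradient_amplitude = 0.2,
                  noise_sd = 0)
  tg <- generate_tile(sp, seed = 8)
  err_u <- max_profile_error(quantify_tile(tg$tile, correct = FALSE),
                             tg$truth$fractions)
  err_c <- max_profile_error(quantify_tile(tg$tile, correct = TRUE),
                             tg$truth$fractions)
  expect_lt(err_c, 1)
  expect_lt(err_c, err_u)
})

test_that("flat and degenerate tiles pass through illumination correction", {
  const <- ihc_tile(array(130, c(24, 24, 3)))
  out <- correct_illumination(const)
  expect_lt(max(abs(out$px - const$px)), 1)

  white <- ihc_tile(array(255, c(16, 16, 3)))
  flagged <- correct_illumination(white)
  expect_true(attr(flagged, "illumination_flagged"))
  expect_identical(flagged$px, white$px)

  black <- ihc_tile(array(0, c(16, 16, 3)))
  expect_true(attr(correct_illumination(black), "illumination_flagged"))
})

test_that("raising the positive threshold never increases positive area", {
  tg <- generate_tile(tile_spec(width = 48, height = 48), seed = 12)
  od <- separate_stains(correct_illumination(tg$tile))
  pos <- vapply(seq(0.05, 0.5, by = 0.05), function(t1) {
    quantify_areas(classify_pixels(od, intensity_thresholds(
      od_positive = t1, od_weak_mod = 0.6, od_mod_strong = 0.9)))$pct_total_positive
  }, numeric(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("the tissue mask excludes glass from the analyzed area", {
  sp <- tile_spec(width = 40, height = 40,
                  class_fractions = c(negative = 0.3, weak = 0.3,
                                      moderate = 0.2, strong = 0.1),
                  background_fraction = 0.1,
                  gradient_amplitude = 0, noise_sd = 0)
  tg <- generate_tile(sp, seed = 13)
  mask <- tissue_mask(tg$tile)
  expect_equal(sum(!mask), sum(tg$truth$labels == "background"))
  prof <- quantify_tile(tg$tile, correct = FALSE, mask = mask)
  expect_equal(profile_vec(prof), unname(tg$truth$fractions))
})
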
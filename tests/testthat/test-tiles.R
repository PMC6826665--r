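test_that("an all-negative noise-free spec renders a fully negative tile", {
  sp <- tile_spec(width = 24, height = 24,
                  class_fractions = c(negative = 1, weak = 0, moderate = 0,
                                      strong = 0),
                  gradient_amplitude = 0, noise_sd = 0)
  tg <- generate_tile(sp, seed = 1)
  expect_true(all(tg$truth$labels == "negative"))
  expect_equal(unname(tg$truth$fractions), c(100, 0, 0, 0))
})

test_that("hard-edged class pixel counts match the requested fractions exactly", {
  sp <- tile_spec(width = 50, height = 40,
                  class_fractions = c(negative = 0.4, weak = 0.3,
                                      moderate = 0.2, strong = 0.1),
                  gradient_amplitude = 0, noise_sd = 0)
  tg <- generate_tile(sp, seed = 2)
  counts <- table(tg$truth$labels)
  expect_equal(unname(counts[c("negative", "weak", "moderate", "strong")]),
               as.table(c(800, 600, 400, 200)), ignore_attr = TRUE)
})

test_that("fractions not summing to one are rejected", {
  expect_error(tile_spec(class_fractions = c(negative = 0.5, weak = 0.3,
                                             moderate = 0.2, strong = 0.2)),
               "sum to 1")
  expect_error(tile_spec(class_fractions = c(negative = 0.9, weak = 0.1)),
               "must name")
})

test_that("tile generation is seed-deterministic", {
  sp <- tile_spec(width = 32, height = 32)
  expect_identical(generate_tile(sp, seed = 9), generate_tile(sp, seed = 9))
  expect_false(identical(generate_tile(sp, seed = 9)$tile$px,
                         generate_tile(sp, seed = 10)$tile$px))
})

test_that("tiles survive a PNG write/read round trip", {
  tg <- generate_tile(tile_spec(width = 20, height = 20), seed = 4)
  path <- withr::local_tempfile(fileext = ".png")
  write_tile(tg$tile, path)
  back <- read_tile(path, tumor_id = "T001", marker = "calponin",
                    field_index = 1)
  expect_equal(back$px, tg$tile$px, ignore_attr = TRUE)
})

test_that("cell layouts are painted with a faithful annotation table", {
  layout <- list(
    list(center = c(12, 12), shape = "spindle", category = "SME",
         intensity = "mild", size = 2, axis_ratio = 4),
    list(center = c(34, 30), shape = "polygonal", category = "HME",
         intensity = "marked", size = 4, axis_ratio = 1.2),
    list(center = c(20, 36), shape = "polygonal", category = "NME",
         intensity = "moderate", size = 3, axis_ratio = 1.5))
  sp <- tile_spec(width = 48, height = 48, cell_layout = layout,
                  gradient_amplitude = 0, noise_sd = 0)
  tg <- generate_tile(sp, seed = 5)
  expect_equal(nrow(tg$truth$cells), 3)
  expect_equal(tg$truth$cells$category, c("SME", "HME", "NME"))
  # rendered intensity class matches the requested one
  expect_true(any(tg$truth$labels == "weak"))
  expect_true(any(tg$truth$labels == "strong"))
  # shape recovered from the true axis ratios
  got <- classify_cell_shape(tg$truth$cells$axis_ratio)
  expect_equal(as.character(got), c("spindle", "polygonal", "polygonal"))
})

test_that("cell records realize requested percentages with exact counts", {
  recs <- generate_cell_records(c(sme = 50, hme = 25, nme = 25),
                                marker = "calponin", n_cells = 200, seed = 1)
  expect_equal(unname(table(recs$category)), as.table(c(100, 50, 50)),
               ignore_attr = TRUE)
  sma <- generate_cell_records(c(sme = 60, hme = 40, nme = 0),
                               marker = "sma", n_cells = 150, seed = 2)
  expect_true(all(sma$category %in% c("SME", "HME")))
  expect_error(
    generate_cell_records(c(sme = 50, hme = 25, nme = 25), marker = "sma"),
    "does not label neoplastic")
})

test_that("cell record aggregation round-trips the generating percentages", {
  coh <- generate_cohort(cohort_params(), seed = 6)
  for (i in c(1, 20, 50)) {
    n_cells <- 400
    recs <- generate_cell_records(coh[i, ], marker = "calponin",
                                  n_cells = n_cells, seed = i)
    agg <- aggregate_cell_percentages(recs)
    expect_lt(abs(agg$pct_sme - coh$calponin_pct_sme[i]), 100 / n_cells)
    expect_lt(abs(agg$pct_nme - coh$calponin_pct_nme[i]), 100 / n_cells)
  }
})
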
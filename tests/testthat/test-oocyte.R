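test_that("phase classification follows size bands, appearance and stage", {
  expect_equal(classify_phase(c(250, 400, 800, 1600)),
               c("primary", "transitional", "secondary", "maturation"))
  expect_equal(classify_phase(250, appearance = "transparent"), "primary")
  expect_equal(classify_phase(400, appearance = "translucent"),
               "transitional")
  # half-open boundaries: 300 um is already transitional, 500 secondary
  expect_equal(classify_phase(c(300, 500, 1500)),
               c("transitional", "secondary", "maturation"))
  # the 1200-1500 um overlap is decided by appearance
  expect_equal(classify_phase(1300, appearance = "translucent"),
               "maturation")
  expect_equal(classify_phase(1300, appearance = "opaque"), "secondary")
  # a decisive histology stage overrides size
  expect_equal(classify_phase(450, histology_stage = "V2"), "secondary")
  expect_equal(classify_phase(1000, histology_stage = "H"), "maturation")
  expect_error(classify_phase(-5), class = "fecundr_domain_error")
  expect_error(classify_phase(400, appearance = "shiny"),
               class = "fecundr_validation_error")
})

test_that("classification is total and deterministic on valid input", {
  set.seed(11)
  d <- runif(500, 1, 2000)
  app <- sample(c("transparent", "translucent", "opaque", NA), 500,
                replace = TRUE)
  ph <- classify_phase(d, app)
  expect_false(anyNA(ph))
  expect_true(all(ph %in% c("primary", "transitional", "secondary",
                            "maturation")))
  expect_identical(ph, classify_phase(d, app))
})

test_that("histograms bin, floor and conserve counts", {
  oo <- tibble::tibble(fish_id = "f", diameter_um = c(150, 350, 800),
                       phase = NA_character_,
                       histology_stage = NA_character_)
  h <- build_histogram(oo, bin_width = 100, measurement_floor = 100)
  nonzero <- h[h$count > 0, ]
  expect_equal(nonzero$bin_start, c(100, 300, 800))
  expect_equal(nonzero$count, rep(1L, 3))
  expect_equal(nonzero$phase, c("primary", "transitional", "secondary"))
  expect_equal(attr(h, "n_excluded"), 0L)

  h2 <- build_histogram(oo, bin_width = 100, measurement_floor = 400)
  expect_equal(attr(h2, "n_excluded"), 2L)
  expect_equal(sum(h2$count), 1L)
  expect_equal(h2$bin_start[h2$count > 0], 800)

  expect_equal(nrow(build_histogram(oo[0, ])), 0)

  # conservation: excluded + binned = input, over random inputs
  set.seed(21)
  for (i in 1:5) {
    oo <- tibble::tibble(diameter_um = runif(200, 10, 1800))
    h <- build_histogram(oo, bin_width = 50, measurement_floor = 100)
    expect_equal(sum(h$count) + attr(h, "n_excluded"), 200L)
  }
})

test_that("gap uncertainty is the transitional share, scale-invariant", {
  expect_equal(gap_uncertainty(0, 200), 0)
  expect_equal(gap_uncertainty(8, 92), 8)
  expect_equal(gap_uncertainty(5, 95), 5)
  expect_warning(gu <- gap_uncertainty(0, 0))
  expect_true(is.na(gu))
  for (k in c(2, 7, 100)) {
    expect_equal(gap_uncertainty(8 * k, 92 * k), gap_uncertainty(8, 92))
  }
  expect_error(gap_uncertainty(-1, 5), class = "fecundr_domain_error")
})

test_that("size-gap detection reads the transitional band", {
  oo <- tibble::tibble(diameter_um = c(rep(150, 20), rep(900, 95),
                                       rep(420, 5)))
  h <- build_histogram(oo, bin_width = 50, measurement_floor = 100)
  rep1 <- detect_size_gap(h, band = c(300, 500))
  expect_false(rep1$complete_gap)
  expect_equal(rep1$band_transitional, 5L)
  expect_equal(rep1$gap_uncertainty, 5)

  oo2 <- tibble::tibble(diameter_um = c(rep(150, 20), rep(900, 95)))
  h2 <- build_histogram(oo2, bin_width = 50, measurement_floor = 100)
  rep2 <- detect_size_gap(h2, band = c(300, 500))
  expect_true(rep2$complete_gap)
  expect_equal(rep2$band_count, 0L)
  expect_equal(rep2$gap_uncertainty, 0)

  expect_error(detect_size_gap(h2, band = c(0, 500)),
               class = "fecundr_range_error")
})

test_that("synthetic ovaries show / hide the size gap by synchrony mode", {
  # group synchrony: once recruitment completes the transitional band is
  # empty in a pre-spawning-style profile
  cfg <- synthetic_config(n_fish = 12, seed = 5, sampling_dates = 15,
                          n_per_date = 12)
  pop <- suppressMessages(suppressWarnings(generate_population(cfg)))
  oo <- pop$survey$oocytes
  h <- build_histogram(oo, bin_width = 50, measurement_floor = 100)
  expect_true(detect_size_gap(h, cfg$gap_band)$complete_gap)

  # asynchrony: the de novo pipeline keeps the band occupied mid-run
  cfg2 <- synthetic_config(mode = "asynchronous", n_fish = 12, seed = 5,
                           sampling_dates = 15, n_per_date = 12)
  pop2 <- suppressMessages(suppressWarnings(generate_population(cfg2)))
  h2 <- build_histogram(pop2$survey$oocytes, bin_width = 50,
                        measurement_floor = 100)
  expect_false(detect_size_gap(h2, cfg2$gap_band)$complete_gap)
})
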
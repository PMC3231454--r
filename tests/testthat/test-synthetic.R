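test_that("chemistry generation is deterministic and respects the ranges", {
  cfg <- synthetic_config(seed = 5)
  a <- generate_chemistry(cfg)
  b <- generate_chemistry(cfg)
  expect_identical(a$reference, b$reference)
  expect_equal(nrow(a$reference), 363)
  # large draw stays inside the calibration ranges for every analyte
  big <- generate_chemistry(synthetic_config(
    n_per_season = c(3400, 3300, 3300), seed = 6))$reference
  ranges <- list(ssc_brix = c(10.60, 58.60),
                 reducing_sugar_gL = c(81.50, 586.40), ph = c(2.48, 4.60),
                 titratable_acidity_gL = c(0.20, 20.50),
                 tartaric_gL = c(4.90, 18.60), malic_gL = c(0.10, 14.50),
                 potassium_mgL = c(841.00, 2737.00))
  for (a_ in names(ranges)) {
    expect_gte(min(big[[a_]]), ranges[[a_]][1])
    expect_lte(max(big[[a_]]), ranges[[a_]][2])
  }
  # ripening trajectories: sugars up, acidity down
  expect_lt(cor(big$ssc_brix, big$titratable_acidity_gL), 0)
  expect_gt(cor(big$ssc_brix, big$reducing_sugar_gL), 0.9)
})

test_that("spectra are background-only at zero concentration and noise", {
  cfg <- synthetic_config(n_per_season = 3, seasons = 2008, n_varieties = 1,
                          replicates = 1, presentations = "must",
                          mult_sd = 0, add_sd = 0, tilt_sd = 0, noise_sd = 0,
                          nonlinearity = 0, seed = 1)
  ref <- reference_table(data.frame(sample_id = c("A", "B", "C"),
                                    ssc_brix = 0, reducing_sugar_gL = 0,
                                    ph = 0, titratable_acidity_gL = 0,
                                    tartaric_gL = 0, malic_gL = 0,
                                    potassium_mgL = 0))
  meta <- data.frame(sample_id = c("A", "B", "C"), variety = "V1",
                     variety_class = "white", season = 2008,
                     date = "2008-08-01", ripeness = 0.5)
  sp <- generate_spectra(ref, meta, band_library(), cfg)
  expect_equal(sp$x[1, ], sp$x[2, ])
  expect_equal(sp$x[1, ], sp$x[3, ])
})

test_that("band contributions are linear in concentration without the
           nonlinearity", {
  cfg <- synthetic_config(n_per_season = 2, seasons = 2008, n_varieties = 1,
                          replicates = 1, presentations = "must",
                          mult_sd = 0, add_sd = 0, tilt_sd = 0, noise_sd = 0,
                          nonlinearity = 0, seed = 1)
  base <- data.frame(sample_id = c("A", "B"), ssc_brix = 0,
                     reducing_sugar_gL = 0, ph = 0,
                     titratable_acidity_gL = c(5, 10), tartaric_gL = 0,
                     malic_gL = 0, potassium_mgL = 0)
  meta <- data.frame(sample_id = c("A", "B"), variety = "V1",
                     variety_class = "white", season = 2008,
                     date = "2008-08-01", ripeness = 0.5)
  sp <- generate_spectra(reference_table(base), meta, band_library(), cfg)
  zero <- base; zero$titratable_acidity_gL <- 0
  bg <- generate_spectra(reference_table(zero), meta, band_library(), cfg)
  d1 <- sp$x[1, ] - bg$x[1, ]
  d2 <- sp$x[2, ] - bg$x[2, ]
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("a study regenerates byte-identically from its seed", {
  cfg <- fixture_config(seed = 9)
  d1 <- file.path(tempdir(), "gn_det1"); d2 <- file.path(tempdir(), "gn_det2")
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  expect_identical(readLines(file.path(d1, "spectra.csv")),
                   readLines(file.path(d2, "spectra.csv")))
  expect_identical(readLines(file.path(d1, "reference.csv")),
                   readLines(file.path(d2, "reference.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the default study matches the campaign accounting", {
  st <- gn_study(0.15)
  expect_equal(nrow(st$chem$reference), 363)
  expect_equal(as.vector(table(st$chem$meta$season)), c(108, 120, 135))
  expect_equal(length(unique(st$chem$meta$variety)), 25)
  expect_equal(n_spectra(st$avg), 363)
})

test_that("the fixture study runs the full pipeline quickly", {
  fx <- gn_fixture_paths()
  out_dir <- file.path(tempdir(), "gn_smoke")
  cfg <- study_config(fx$spectra, fx$reference,
                      analytes = "ssc_brix",
                      treatments = "2,5,5,1",
                      windows = list(c(380, 1650)),
                      validation_fraction = 0.3,
                      max_factors = 5, local_k = c(15, 18), local_l = 6,
                      n_discard = 4, out_dir = out_dir, seed = 2)
  res <- run_study(cfg)
  expect_true(all(c("calibration_table", "validation_table", "local_grids")
                  %in% names(res)))
  expect_true(file.exists(file.path(out_dir, "calibration_stats.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  unlink(out_dir, recursive = TRUE)
})
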
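test_that("spectra CSV loading keeps shapes and validates the grid", {
  dir <- withr::local_tempdir()
  sp_path <- file.path(dir, "spectra.csv")
  writeLines(c("sample_id,replicate,variety,season,date,presentation,380,382,384",
               "A,1,V1,2008,2008-08-01,bunch,0.1,0.2,0.3",
               "B,1,V1,2008,2008-08-01,bunch,0.4,0.5,0.6"), sp_path)
  ref_path <- file.path(dir, "reference.csv")
  writeLines(c("sample_id,ssc_brix,reducing_sugar_gL,ph,titratable_acidity_gL,tartaric_gL,malic_gL,potassium_mgL",
               "A,20,190,3.3,6,9,2,1500",
               "B,22,210,3.4,5,8,1.5,1600"), ref_path)
  ds <- load_dataset(sp_path, ref_path)
  expect_identical(dim(ds$spectra$x), c(2L, 3L))
  expect_equal(ds$spectra$wavelengths, c(380, 382, 384))
  expect_length(ds$excluded, 0)

  # non-uniform grid is rejected
  bad <- file.path(dir, "bad.csv")
  writeLines(c("sample_id,replicate,presentation,380,382,390",
               "A,1,bunch,0.1,0.2,0.3"), bad)
  expect_error(load_dataset(bad, ref_path), "non-uniform")
})

test_that("samples without reference chemistry are excluded with a warning", {
  dir <- withr::local_tempdir()
  sp_path <- file.path(dir, "spectra.csv")
  writeLines(c("sample_id,replicate,variety,season,date,presentation,380,382",
               "A,1,V1,2008,2008-08-01,bunch,0.1,0.2",
               "ORPHAN,1,V1,2008,2008-08-01,bunch,0.3,0.4"), sp_path)
  ref_path <- file.path(dir, "reference.csv")
  writeLines(c("sample_id,ssc_brix", "A,20"), ref_path)
  expect_warning(ds <- load_dataset(sp_path, ref_path), "no reference")
  expect_identical(ds$excluded, "ORPHAN")
  expect_identical(ds$spectra$meta$sample_id, "A")
})

test_that("a generated study round-trips through the CSV dialect", {
  fx <- gn_fixture_paths()
  ds <- load_dataset(fx$spectra, fx$reference)
  orig <- fx$spectra_set
  expect_equal(ds$spectra$x, orig$x, tolerance = 1e-9)
  expect_equal(ds$spectra$wavelengths, orig$wavelengths)
  expect_identical(ds$spectra$meta$sample_id, orig$meta$sample_id)
  expect_equal(ds$reference$ssc_brix, fx$reference_table$ssc_brix,
               tolerance = 1e-9)
})

test_that("replicate averaging is the per-wavelength mean", {
  s <- gn_tiny_set(n = 1)
  x8 <- s$x[rep(1, 8), , drop = FALSE]
  meta8 <- s$meta[rep(1, 8), ]; meta8$replicate <- 1:8
  s8 <- spectra_set(x8, s$wavelengths, meta8)
  avg <- average_replicates(s8)
  expect_equal(n_spectra(avg), 1)
  expect_equal(avg$x[1, ], s$x[1, ])
  expect_equal(avg$meta$n_replicates, 8)

  # antisymmetric replicates cancel
  s2 <- spectra_set(rbind(s$x[1, ], -s$x[1, ]), s$wavelengths,
                    data.frame(sample_id = "A", replicate = 1:2,
                               presentation = "must"))
  expect_equal(max(abs(average_replicates(s2)$x)), 0)
})

test_that("averaging 8 noisy replicates shrinks noise like 1/sqrt(8)", {
  p <- 50; sigma <- 0.05; n_samples <- 300
  x <- with_test_seed(99, matrix(rnorm(n_samples * 8 * p, 0, sigma),
                                 n_samples * 8, p))
  meta <- data.frame(sample_id = rep(sprintf("S%03d", 1:n_samples), each = 8),
                     replicate = rep(1:8, n_samples), presentation = "bunch")
  avg <- average_replicates(spectra_set(x, seq(380, by = 2, length.out = p),
                                        meta))
  # mean deviates from the zero base spectrum by ~ sigma/sqrt(8)
  expect_equal(sqrt(mean(avg$x^2)), sigma / sqrt(8), tolerance = 0.05)
})

test_that("conflicting metadata within a replicate group is an error", {
  s <- gn_tiny_set(n = 2)
  s$meta$sample_id <- "A"
  s$meta$variety <- c("V1", "V2")
  expect_error(average_replicates(s), "conflicting metadata")
})

test_that("window slicing keeps closed-interval endpoints and composes", {
  wl <- seq(380, 1700, by = 2)
  s <- spectra_set(matrix(seq_along(wl), 1), wl,
                   data.frame(sample_id = "A"))
  s1 <- slice_range(s, 380, 1650)
  expect_length(s1$wavelengths, 636)
  expect_equal(range(s1$wavelengths), c(380, 1650))
  # nested slices collapse to the innermost
  a <- slice_range(slice_range(s, 780, 1650), 1100, 1650)
  b <- slice_range(s, 1100, 1650)
  expect_equal(a$x, b$x)
  expect_equal(a$wavelengths, b$wavelengths)
  # full-grid slice is the identity
  expect_equal(slice_range(s, 380, 1700)$x, s$x)
  expect_error(slice_range(s, 1701, 1800), "intersect")
})

test_that("replicate averaging commutes with window slicing", {
  fx <- gn_fixture_paths()
  s <- fx$spectra_set
  a <- slice_range(average_replicates(s), 780, 1650)
  b <- average_replicates(slice_range(s, 780, 1650))
  expect_equal(a$x, b$x)
  expect_equal(a$wavelengths, b$wavelengths)
})
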
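lib_set <- function(x, ids = sprintf("L%03d", seq_len(nrow(x)))) {
  spectra_set(x, seq(380, by = 2, length.out = ncol(x)),
              data.frame(sample_id = ids), check_step = TRUE)
}

test_that("neighbor selection ranks by Pearson correlation", {
  x <- with_test_seed(20, matrix(rnorm(20 * 50), 20, 50))
  lib <- lib_set(x)
  # query identical to a library spectrum
  nb <- select_neighbors(lib, x[7, ], k = 1)
  expect_identical(nb$ids, "L007")
  expect_equal(nb$correlations, 1)
  # the negated spectrum ranks last
  nb_all <- select_neighbors(lib, -x[7, ], k = 20)
  expect_identical(nb_all$ids[20], "L007")
  expect_equal(nb_all$correlations[20], -1)
  # brute-force oracle for the full ranking
  q <- with_test_seed(21, rnorm(50))
  r <- apply(x, 1, function(row) cor(row, q))
  oracle <- lib$meta$sample_id[order(-r)][1:5]
  expect_identical(select_neighbors(lib, q, 5)$ids, oracle)
  expect_error(select_neighbors(lib, q, 21), "exceeds")
})

test_that("a library with one shared reference value predicts it exactly", {
  x <- with_test_seed(22, matrix(rep(rnorm(30), each = 20), 20, 30))
  lib <- lib_set(x)
  cfg <- local_config(k = 16, l_max = 16, min_library = 15)
  p <- local_predict(lib, rep(4.2, 20), x[1, ] + 0, cfg)
  expect_equal(p$value, 4.2)
})

test_that("LOCAL prediction is a convex combination of per-factor predictions", {
  x <- with_test_seed(23, matrix(rnorm(60 * 40), 60, 40))
  y <- x[, 3] + 0.2 * x[, 10] + with_test_seed(24, rnorm(60, 0, 0.1))
  lib <- lib_set(x)
  q <- with_test_seed(25, rnorm(40))
  cfg <- local_config(k = 30, l_max = 10, n_discard = 4, weighting = "shenk")
  p <- local_predict(lib, y, q, cfg)
  expect_length(p$per_factor_predictions, 10 - 4)
  expect_equal(sum(p$weights), 1)
  expect_true(all(p$weights >= 0))
  expect_gte(p$value, min(p$per_factor_predictions))
  expect_lte(p$value, max(p$per_factor_predictions))
  expect_equal(p$value, sum(p$weights * p$per_factor_predictions))
  # with a single retained factor count the average is that prediction
  cfg1 <- local_config(k = 30, l_max = 5, n_discard = 4,
                       weighting = "uniform")
  p1 <- local_predict(lib, y, q, cfg1)
  expect_equal(p1$value, p1$per_factor_predictions[1])
  # GH/NH attached
  expect_true(is.finite(p$gh) && is.finite(p$nh))
  # too small a usable library is refused
  y_na <- y; y_na[1:50] <- NA
  expect_error(local_predict(lib, y_na, q, cfg), "insufficient library")
})

test_that("LOCAL with the whole library reduces to the global model per factor", {
  x <- with_test_seed(26, matrix(rnorm(50 * 45), 50, 45))
  y <- x[, 2] - 0.6 * x[, 30] + with_test_seed(27, rnorm(50, 0, 0.05))
  lib <- lib_set(x)
  q <- with_test_seed(28, rnorm(45))
  for (mode in c("pls", "mpls")) {
    cfg <- local_config(k = 50, l_max = 8, n_discard = 4, mode = mode)
    p <- local_predict(lib, y, q, cfg)
    global <- fit_pls1(x, y, 8, mode)
    expect_equal(p$per_factor_predictions,
                 vapply(5:8, function(j) predict_pls(global, q, j),
                        numeric(1)),
                 tolerance = 1e-8)
  }
})

test_that("the optimization grid enumerates cells and flags sub-minimum k", {
  x <- with_test_seed(29, matrix(rnorm(40 * 30), 40, 30))
  y <- x[, 4] + with_test_seed(30, rnorm(40, 0, 0.1))
  lib <- lib_set(x[1:30, ])
  val <- lib_set(x[31:40, ], ids = sprintf("V%03d", 1:10))
  og <- optimize_local_grid(lib, y[1:30], val, y[31:40],
                            k_grid = c(20, 25, 30), l_grid = c(6, 8),
                            cfg = local_config(k = 20, l_max = 8,
                                               n_discard = 4))
  expect_equal(nrow(og$grid), 6)
  expect_equal(og$best$sepc, min(og$grid$sepc))
  # single cell returns trivially
  og1 <- optimize_local_grid(lib, y[1:30], val, y[31:40],
                             k_grid = 25, l_grid = 8,
                             cfg = local_config(k = 25, l_max = 8))
  expect_equal(nrow(og1$grid), 1)
  # k below min_library is skipped with a warning
  expect_warning(
    og2 <- optimize_local_grid(lib, y[1:30], val, y[31:40],
                               k_grid = c(10, 25), l_grid = 8,
                               cfg = local_config(k = 25, l_max = 8)),
    "min_library")
  expect_equal(nrow(og2$grid), 1)
  expect_error(optimize_local_grid(lib, y[1:30], lib, y[1:30],
                                   k_grid = 25, l_grid = 8), "disjoint")
})
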
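rand_problem <- function(n, p, seed) {
  with_test_seed(seed, list(X = matrix(rnorm(n * p), n, p), y = rnorm(n)))
}

test_that("PLS1 represents exactly linear band structure and matches OLS at
           full rank", {
  # orthonormal centered design: y in the span of two columns is fit
  # exactly by two factors
  Q <- with_test_seed(10, qr.Q(qr(scale(matrix(rnorm(400), 40, 10),
                                       scale = FALSE))))
  y <- 2 * Q[, 3] - 0.5 * Q[, 7] + 1
  m <- fit_pls1(Q, y, n_factors = 2, mode = "pls")
  expect_lt(max(abs(m$fitted[, 2] - y)), 1e-8)

  # full-factor PLS predictions equal least squares
  pr2 <- rand_problem(30, 8, 11)
  m2 <- fit_pls1(pr2$X, pr2$y, n_factors = 8, mode = "pls")
  beta <- lm.fit(cbind(1, pr2$X), pr2$y)$coefficients
  Xt <- rand_problem(5, 8, 12)$X
  expect_equal(predict_pls(m2, Xt, 8),
               drop(cbind(1, Xt) %*% beta), tolerance = 1e-6)
})

test_that("PLS and MPLS regression vectors are invariant to duplicating
           every sample", {
  pr <- rand_problem(25, 15, 13)
  for (mode in c("pls", "mpls")) {
    m1 <- fit_pls1(pr$X, pr$y, 5, mode)
    m2 <- fit_pls1(pr$X[rep(1:25, 2), ], rep(pr$y, 2), 5, mode)
    expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-9)
  }
})

test_that("prediction respects centering identities", {
  pr <- rand_problem(20, 12, 14)
  m <- fit_pls1(pr$X, pr$y, 4, "mpls")
  expect_equal(predict_pls(m, m$x_mean, 4), m$y_mean, tolerance = 1e-10)
  expect_equal(predict_pls(m, pr$X, 0), rep(m$y_mean, 20))
  # pure function: repeated calls agree
  expect_identical(predict_pls(m, pr$X, 3), predict_pls(m, pr$X, 3))
  # shifting y shifts predictions by the same constant
  m2 <- fit_pls1(pr$X, pr$y + 100, 4, "mpls")
  expect_equal(predict_pls(m2, pr$X, 4), predict_pls(m, pr$X, 4) + 100,
               tolerance = 1e-9)
  expect_error(predict_pls(m, pr$X[, 1:5], 2), "grid")
  expect_error(fit_pls1(pr$X, rep(1, 20), 2), "zero-variance")
})

test_that("MPLS differs from plain PLS beyond the first factor", {
  pr <- rand_problem(30, 20, 15)
  mp <- fit_pls1(pr$X, pr$y, 4, "pls")
  mm <- fit_pls1(pr$X, pr$y, 4, "mpls")
  expect_equal(mp$coefficients[, 1], mm$coefficients[, 1], tolerance = 1e-10)
  expect_gt(max(abs(mp$coefficients[, 3] - mm$coefficients[, 3])), 1e-8)
})

test_that("cross-validation handles constant and noise responses sensibly", {
  pr <- rand_problem(40, 10, 16)
  cv_const <- cross_validate(pr$X, rep(3.3, 40), max_factors = 5, seed = 1)
  expect_equal(cv_const$secv_by_factors, rep(0, 5))
  expect_equal(cv_const$chosen_factors, 1L)

  # pure-noise y: chosen factor count stays small (median over seeds)
  chosen <- vapply(1:9, function(s) {
    pr2 <- rand_problem(40, 10, 100 + s)
    cross_validate(pr2$X, pr2$y, max_factors = 8, seed = s)$chosen_factors
  }, integer(1))
  expect_lte(median(chosen), 3)
  # ... and late-factor SECV exceeds the early minimum (overfitting visible)
  worse <- vapply(1:9, function(s) {
    pr2 <- rand_problem(40, 10, 100 + s)
    secv <- cross_validate(pr2$X, pr2$y, max_factors = 8,
                           seed = s)$secv_by_factors
    secv[8] >= min(secv[1:2])
  }, logical(1))
  expect_gte(mean(worse), 0.5)
})

test_that("cross-validation recovers high-SNR linear structure and SEC stays
           below SECV", {
  # band-structured spectra: three Gaussian bands with random concentrations
  set <- with_test_seed(17, {
    wl <- seq_len(100)
    bands <- sapply(c(25, 50, 80), function(cen) exp(-0.5 * ((wl - cen) / 8)^2))
    conc <- matrix(runif(60 * 3, 1, 5), 60, 3)
    X <- conc %*% t(bands) + matrix(rnorm(60 * 100, 0, 0.002), 60, 100)
    list(X = X, y = conc[, 1] + rnorm(60, 0, 0.02))
  })
  cv <- cross_validate(set$X, set$y, max_factors = 16, seed = 2, mode = "mpls")
  expect_gte(cv$r2_cv, 0.95)
  expect_lte(cv$sec, cv$secv * 1.05)
  expect_error(cross_validate(set$X[1:7, ], set$y[1:7]), "at least 2 samples")
})

test_that("group assignment is seeded and partitions the calibration set", {
  pr <- rand_problem(41, 8, 18)
  cv1 <- cross_validate(pr$X, pr$y, max_factors = 5, seed = 7)
  cv2 <- cross_validate(pr$X, pr$y, max_factors = 5, seed = 7)
  cv3 <- cross_validate(pr$X, pr$y, max_factors = 5, seed = 8)
  expect_identical(cv1$groups, cv2$groups)
  expect_false(identical(cv1$groups, cv3$groups))
  expect_setequal(unique(cv1$groups), 1:4)
  expect_true(all(table(cv1$groups) >= 10))
})
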
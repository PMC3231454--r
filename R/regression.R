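#' Fit a PLS1 or modified-PLS (MPLS) calibration
#'
#' Sequential NIPALS factor extraction on column-centered spectra and a
#' centered univariate response. In `mpls` mode, after each factor is
#' removed the spectral residual of every wavelength is rescaled by its
#' standard deviation (the Shenk-Westerhaus modification), so later factors
#' weight all wavelengths' remaining information equally. The model stores
#' a regression vector for every factor count `j <= n_factors`, so
#' predictions at reduced rank need no refitting.
#'
#' @param X numeric matrix of pretreated spectra (samples x wavelengths).
#' @param y numeric response, one value per row of `X` (analyte units).
#' @param n_factors number of latent factors to extract (default 16,
#'   the usual cap for these calibrations); must be < `nrow(X)`.
#' @param mode `"pls"` (classical PLS1) or `"mpls"`.
#' @return a `PLSModel`: list with `mode`, `n_factors`, `x_mean`, `y_mean`,
#'   `coefficients` (wavelengths x n_factors; column j is the regression
#'   vector using j factors, on the original X scale), `rms_x_residual`
#'   (RMS spectral residual after each factor, on the working scale),
#'   `coef_norms`, and `fitted` (training predictions per factor count).
#' @export
fit_pls1 <- function(X, y, n_factors = 16, mode = c("pls", "mpls")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n_factors >= n) stop("n_factors must be smaller than the sample count")
  if (stats::sd(y) == 0) stop("zero-variance response")

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)          # spectral residual, working scale
  f <- y - y_mean                   # response residual
  A <- as.integer(n_factors)

  W <- P <- matrix(0.0, p, A)       # weights / loadings on the working scale
  q <- numeric(A)
  scale_sd <- matrix(1.0, p, A)     # per-column sd divided out before factor a
  rms_x <- numeric(A)

  for (a in seq_len(A)) {
    if (mode == "mpls" && a > 1) {
      sds <- sqrt(pmax(colMeans(E^2) - colMeans(E)^2, 0))
      sds[sds < 1e-12] <- 1
      scale_sd[, a] <- sds
      E <- sweep(E, 2, sds, "/")
    }
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {      # response fully explained; degenerate factor = 0
      rms_x[a] <- sqrt(mean(E^2))
      next
    }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - t * q[a]
    W[, a] <- w; P[, a] <- pl
    rms_x[a] <- sqrt(mean(E^2))
  }

  # Regression vectors on the original (centered) X scale. With
  # D_a = diag(1/scale_sd[,a]) the residual map is
  #   z_1 = x_c;  t_a = w_a' z_a;  z_{a+1} = D_{a+1} (I - p_a w_a') z_a
  # so the score row r_a (t_a = r_a' x_c) unwinds backward:
  #   v <- w_a;  for k = a..2: v <- v / sd_k; v <- v - (v . p_{k-1}) w_{k-1}
  # and b_j = sum_{a<=j} q_a r_a.
  R <- matrix(0.0, p, A)
  for (a in seq_len(A)) {
    v <- W[, a]
    if (a >= 2) {
      for (k in a:2) {
        v <- v / scale_sd[, k]
        v <- v - sum(v * P[, k - 1]) * W[, k - 1]
      }
    }
    R[, a] <- v
  }
  coefs <- matrix(0.0, p, A)
  acc <- numeric(p)
  for (a in seq_len(A)) {
    acc <- acc + q[a] * R[, a]
    coefs[, a] <- acc
  }

  Xc <- sweep(X, 2, x_mean)
  fitted <- Xc %*% coefs + y_mean
  norms <- sqrt(colSums(coefs^2))

  structure(list(mode = mode, n_factors = A, x_mean = x_mean,
                 y_mean = y_mean, coefficients = coefs,
                 rms_x_residual = rms_x, coef_norms = norms,
                 fitted = fitted),
            class = "PLSModel")
}

#' Predict from a PLSModel at a chosen factor count
#'
#' `y_hat = y_mean + (x - x_mean) . b_j`, with `b_j` the stored regression
#' vector for `j` factors. `j = 0` is allowed as the intercept-only
#' baseline.
#'
#' @param m a `PLSModel`.
#' @param X matrix of spectra on the model grid (or a single spectrum).
#' @param j factor count, `0 <= j <= m$n_factors`; defaults to all factors.
#' @return numeric vector of predictions in analyte units.
#' @export
predict_pls <- function(m, X, j = m$n_factors) {
  stopifnot(inherits(m, "PLSModel"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(m$x_mean))
    stop("spectra are not on the model's wavelength grid")
  if (j < 0 || j > m$n_factors) stop("j must be in 0..n_factors")
  if (j == 0) return(rep(m$y_mean, nrow(X)))
  drop(sweep(X, 2, m$x_mean) %*% m$coefficients[, j] + m$y_mean)
}

#' Grouped cross-validation for factor-count selection
#'
#' The calibration set is shuffled once (seeded) and cut into `n_groups`
#' contiguous blocks; each block is predicted by a model fit on the others,
#' at every candidate factor count. SECV(j) pools the out-of-group residuals
#' (root mean square, denominator n). The chosen factor count is the
#' smallest j whose SECV is within `parsimony` (default 2%) of the minimum,
#' guarding against overfitting with more factors than the data support.
#'
#' @param X pretreated spectra matrix.
#' @param y response vector.
#' @param max_factors largest factor count to evaluate (default 16).
#' @param n_groups number of CV groups (default 4).
#' @param seed integer seed for the group shuffle.
#' @param mode `"pls"` or `"mpls"`.
#' @param parsimony relative tolerance for the factor-selection rule.
#' @return a `CVResult`: list with `secv_by_factors`, `chosen_factors`,
#'   `secv`, `sec`, `r2_cv`, `R2_cal`, `cv_pred` (out-of-group predictions
#'   at the chosen count), `groups`, `seed`, and the refit full-data `model`.
#' @export
cross_validate <- function(X, y, max_factors = 16, n_groups = 4, seed = 1,
                           mode = c("pls", "mpls"), parsimony = 0.02) {
  mode <- match.arg(mode)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2 * n_groups) stop("need at least 2 samples per CV group")
  smallest_fold_train <- n - ceiling(n / n_groups)
  if (max_factors >= smallest_fold_train)
    stop("max_factors too large for the smallest training fold")

  if (stats::sd(y) == 0) {
    # constant response: the mean predicts exactly, no factors needed
    return(structure(list(secv_by_factors = rep(0, max_factors),
                          chosen_factors = 1L, secv = 0, sec = 0,
                          r2_cv = NA_real_, R2_cal = NA_real_,
                          cv_pred = rep(y[1], n), groups = NULL,
                          seed = seed, mode = mode, model = NULL),
                     class = "CVResult"))
  }

  perm <- with_seed(seed, sample.int(n))
  groups <- integer(n)
  bounds <- floor(seq(0, n, length.out = n_groups + 1))
  for (g in seq_len(n_groups))
    groups[perm[(bounds[g] + 1):bounds[g + 1]]] <- g

  cv_pred <- matrix(NA_real_, n, max_factors)
  for (g in seq_len(n_groups)) {
    hold <- groups == g
    m <- fit_pls1(X[!hold, , drop = FALSE], y[!hold], max_factors, mode)
    for (j in seq_len(max_factors))
      cv_pred[hold, j] <- predict_pls(m, X[hold, , drop = FALSE], j)
  }
  secv <- sqrt(colMeans((cv_pred - y)^2))
  best <- min(secv)
  chosen <- which(secv <= best * (1 + parsimony))[1]

  model <- fit_pls1(X, y, max_factors, mode)
  fit_chosen <- model$fitted[, chosen]
  rss <- sum((fit_chosen - y)^2)
  sec <- sqrt(rss / max(n - chosen - 1, 1))
  structure(list(secv_by_factors = secv,
                 chosen_factors = as.integer(chosen),
                 secv = secv[chosen], sec = sec,
                 r2_cv = stats::cor(y, cv_pred[, chosen])^2,
                 R2_cal = stats::cor(y, fit_chosen)^2,
                 cv_pred = cv_pred[, chosen],
                 groups = groups, seed = seed, mode = mode,
                 model = model),
            class = "CVResult")
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
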
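#' Fit a CENTER population model
#'
#' Principal-component analysis of (pretreated) spectra, used to describe
#' the structure and spectral variability of a sample population. The model
#' retains the smallest number of components whose cumulative explained
#' variance reaches `variance_target`, capped at `max_pcs` and at
#' `n_samples - 1`. Scores in this PC space feed the Mahalanobis GH
#' statistic and the spectral-only calibration/validation split.
#'
#' @param s a pretreated `SpectraSet` with at least 3 samples.
#' @param variance_target fraction of variance to capture, in (0, 1];
#'   default 0.99.
#' @param max_pcs upper bound on retained components; default 15.
#' @return a `CenterModel`: list with `mean_spectrum`, `pc_basis`
#'   (orthonormal loadings, one column per PC), `eigenvalues` (score
#'   variances, nonincreasing), `n_pcs`, `n_train`, `wavelengths`.
#' @export
fit_center <- function(s, variance_target = 0.99, max_pcs = 15) {
  n <- n_spectra(s)
  if (n < 3) stop("need at least 3 samples to fit a CENTER model")
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  pc <- stats::prcomp(s$x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[seq_len(min(length(ev), n - 1))]  # drop null dimension
  cum <- cumsum(ev) / sum(ev)
  n_pcs <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(n_pcs)) n_pcs <- length(ev)
  n_pcs <- min(n_pcs, max_pcs, n - 1)
  n_pcs <- max(n_pcs, 1L)
  structure(list(mean_spectrum = pc$center,
                 pc_basis = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 eigenvalues = ev[seq_len(n_pcs)],
                 n_pcs = as.integer(n_pcs),
                 n_train = as.integer(n),
                 wavelengths = s$wavelengths),
            class = "CenterModel")
}

#' Standardized Mahalanobis distance (GH) of spectra to a CENTER model
#'
#' The global H statistic: the squared Mahalanobis distance of a spectrum's
#' PC scores from the population centroid, using the per-component score
#' variances (eigenvalues) as the metric, divided by the number of retained
#' components. Under this normalization the mean GH over the fitting
#' population is (n-1)/n (about 1), and the conventional screening rule
#' flags GH > 3 as a spectral outlier.
#'
#' @param m a `CenterModel`.
#' @param s a `SpectraSet` (or a single numeric spectrum) on the model grid.
#' @return numeric vector of GH values, one per spectrum.
#' @export
gh_distance <- function(m, s) {
  stopifnot(inherits(m, "CenterModel"))
  x <- if (inherits(s, "SpectraSet")) {
    if (length(s$wavelengths) != length(m$wavelengths) ||
        any(abs(s$wavelengths - m$wavelengths) > 1e-8))
      stop("spectra are not on the model's wavelength grid")
    s$x
  } else {
    if (length(s) != length(m$mean_spectrum))
      stop("spectrum length does not match the model grid")
    matrix(s, nrow = 1)
  }
  scores <- sweep(x, 2, m$mean_spectrum) %*% m$pc_basis
  drop(scores^2 %*% (1 / m$eigenvalues)) / m$n_pcs
}

#' Spectral-only calibration/validation split along the GH ranking
#'
#' Orders samples by GH (descending, ties broken by sample_id), then walks
#' the ranking and assigns every `round(1/validation_fraction)`-th sample to
#' the validation set, starting mid-stride so both extremes of the ranking
#' stay in calibration. Samples in the outer ~2% at either end of any
#' retained principal-component score are additionally protected into the
#' calibration set — they mark the boundary of the spectral population — and
#' the next-ranked unprotected sample is taken instead, so the validation
#' count is unchanged. Because assignment follows spectral structure only
#' and boundary samples stay in calibration, reference-value ranges of the
#' validation set nest inside the calibration ranges, the property the
#' selection protocol is chosen for.
#'
#' @param s the `SpectraSet` to split (one row per sample).
#' @param m a `CenterModel` fit on `s` (or a superset on the same grid).
#' @param validation_fraction fraction of samples for validation, in (0, 1).
#' @return a `SplitResult`: list with `calibration_ids`, `validation_ids`
#'   (disjoint, union = all ids), and `gh` (named GH per sample).
#' @export
split_by_center <- function(s, m, validation_fraction) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  ids <- s$meta$sample_id
  if (anyDuplicated(ids)) stop("sample_ids must be unique (average replicates first)")
  gh <- gh_distance(m, s)
  names(gh) <- ids
  step <- max(2L, as.integer(round(1 / validation_fraction)))
  n <- length(ids)
  if (n < 2 * step) stop("too few samples for this validation fraction")
  ord <- order(-gh, ids)                     # GH descending, id tie-break
  scores <- sweep(s$x, 2, m$mean_spectrum) %*% m$pc_basis
  depth <- max(1L, ceiling(0.02 * n))        # ~2% boundary depth per PC
  boundary <- integer(0)                     # PC-boundary samples, capped at
  for (pc in seq_len(ncol(scores))) {        # half the population
    sc <- scores[, pc]
    boundary <- unique(c(boundary, order(sc)[seq_len(depth)],
                         order(-sc)[seq_len(depth)]))
    if (length(boundary) >= n %/% 2) break
  }
  taken <- rep(FALSE, n)                     # ranks unavailable to validation
  taken[c(1L, n, match(boundary, ord))] <- TRUE
  pick <- seq.int(ceiling((step + 1) / 2), n, by = step)
  pick <- pick[pick > 1 & pick < n]          # extremes stay in calibration
  if (!length(pick)) stop("validation set would be empty")
  final <- integer(0)
  for (pk in pick) {                         # substitute protected picks
    cand <- pk
    while (cand <= n && taken[cand]) cand <- cand + 1L
    if (cand > n) {
      cand <- pk
      while (cand >= 1 && taken[cand]) cand <- cand - 1L
    }
    if (cand >= 1 && cand <= n && !taken[cand]) {
      final <- c(final, cand)
      taken[cand] <- TRUE
    }
  }
  if (!length(final)) stop("validation set would be empty")
  val <- sort(ids[ord[final]])
  cal <- sort(setdiff(ids, val))
  structure(list(calibration_ids = cal, validation_ids = val, gh = gh),
            class = "SplitResult")
}

#' Flag spectral outliers by the GH > threshold rule
#'
#' @param gh numeric GH values (e.g. from [gh_distance()]).
#' @param threshold flagging threshold, default 3 (the conventional rule).
#' @return logical vector, `TRUE` where flagged. Flagged samples are
#'   reported, never removed automatically.
#' @export
gh_outliers <- function(gh, threshold = 3) {
  gh > threshold
}
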
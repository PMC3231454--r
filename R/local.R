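#' LOCAL algorithm configuration
#'
#' Tuning parameters for memory-based local calibration: `k` library samples
#' are selected per query by spectral correlation, a local (M)PLS model with
#' `l_max` factors is fitted on them, and the predictions from factor counts
#' `n_discard + 1` through `l_max` are combined into one value. Predictions
#' from the first factors are discarded because low-rank local models are
#' dominated by scatter; the defaults (discard 4, minimum usable library 15)
#' follow standard LOCAL practice for these calibrations.
#'
#' @param k number of neighbors selected per query.
#' @param l_max total PLS factor count of the local model (14-16 typical).
#' @param n_discard early factor predictions dropped from the average.
#' @param min_library smallest admissible library size.
#' @param weighting `"shenk"` (reciprocal of RMS spectral residual times
#'   coefficient norm) or `"uniform"`.
#' @param mode `"mpls"` or `"pls"` for the local fits.
#' @return a `LocalConfig` list.
#' @export
local_config <- function(k = 75, l_max = 16, n_discard = 4, min_library = 15,
                         weighting = c("shenk", "uniform"),
                         mode = c("mpls", "pls")) {
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  if (l_max <= n_discard) stop("l_max must exceed n_discard")
  if (k < min_library) stop("k must be >= min_library")
  structure(list(k = as.integer(k), l_max = as.integer(l_max),
                 n_discard = as.integer(n_discard),
                 min_library = as.integer(min_library),
                 weighting = weighting, mode = mode),
            class = "LocalConfig")
}

#' Select the k library spectra most correlated with a query
#'
#' Ranks library spectra by the Pearson correlation (across wavelengths)
#' between each library spectrum and the query, and returns the top `k`.
#' Ties are broken by sample_id order so selection is deterministic.
#'
#' @param library a pretreated `SpectraSet` (one row per library sample).
#' @param query a single pretreated spectrum (numeric vector on the library
#'   grid).
#' @param k number of neighbors, `k <= n_spectra(library)`.
#' @return list with `ids`, `index` (row indices into the library) and
#'   `correlations`, all ordered by correlation descending.
#' @export
select_neighbors <- function(library, query, k) {
  if (k > n_spectra(library)) stop("k exceeds library size")
  if (length(query) != length(library$wavelengths))
    stop("query is not on the library wavelength grid")
  if (stats::sd(query) == 0) stop("zero-variance query spectrum")
  r <- drop(stats::cor(t(library$x), query))
  if (anyNA(r)) stop("zero-variance library spectrum")
  ord <- order(-r, library$meta$sample_id)
  top <- ord[seq_len(k)]
  list(ids = library$meta$sample_id[top], index = top, correlations = r[top])
}

#' Predict one query spectrum with the LOCAL algorithm
#'
#' Selects the `cfg$k` most correlated library samples, fits a local (M)PLS
#' calibration on them with `cfg$l_max` factors, and averages the
#' predictions from factor counts `cfg$n_discard + 1` to `cfg$l_max`. With
#' `"shenk"` weighting each factor count j is weighted by
#' `1 / (rms X-residual after j factors * ||b_j||)`, normalized to sum to 1,
#' so factor counts that still leave much unexplained spectral variance, or
#' need violent coefficients, count less. GH is the Mahalanobis distance of
#' the query to the whole library population; NH is the same statistic
#' computed in the PC space of the selected neighbors only.
#'
#' @param library a pretreated `SpectraSet` of candidate calibration samples.
#' @param y reference values aligned with the library rows (NA = unusable).
#' @param query a single pretreated spectrum on the library grid.
#' @param cfg a [local_config()].
#' @param center optional `CenterModel` of the library for the GH statistic
#'   (fitted on the fly when omitted).
#' @return a `LocalPrediction`: list with `value`,
#'   `per_factor_predictions`, `weights`, `neighbor_ids`, `correlations`,
#'   `gh`, `nh`.
#' @export
local_predict <- function(library, y, query, cfg, center = NULL) {
  stopifnot(inherits(cfg, "LocalConfig"))
  usable <- !is.na(y)
  if (sum(usable) < cfg$min_library)
    stop("insufficient library: ", sum(usable), " usable samples < min ",
         cfg$min_library)
  lib <- subset_rows(library, usable)
  yl <- y[usable]
  k <- min(cfg$k, n_spectra(lib))
  if (k < cfg$min_library)
    stop("insufficient library: fewer than min_library usable neighbors")
  nb <- select_neighbors(lib, query, k)
  Xn <- lib$x[nb$index, , drop = FALSE]
  yn <- yl[nb$index]

  jset <- (cfg$n_discard + 1):cfg$l_max
  if (stats::sd(yn) == 0) {
    # all selected neighbors share one reference value: prediction is exact
    return(structure(list(value = yn[1],
                          per_factor_predictions = rep(yn[1], length(jset)),
                          weights = rep(1 / length(jset), length(jset)),
                          neighbor_ids = nb$ids,
                          correlations = nb$correlations,
                          gh = NA_real_, nh = NA_real_),
                     class = "LocalPrediction"))
  }
  m <- fit_pls1(Xn, yn, n_factors = cfg$l_max, mode = cfg$mode)
  preds <- vapply(jset, function(j) predict_pls(m, query, j), numeric(1))

  if (cfg$weighting == "shenk") {
    raw <- 1 / (pmax(m$rms_x_residual[jset], 1e-12) *
                pmax(m$coef_norms[jset], 1e-12))
    w <- raw / sum(raw)
  } else {
    w <- rep(1 / length(jset), length(jset))
  }

  if (is.null(center) && n_spectra(lib) >= 3) center <- fit_center(lib)
  gh <- if (is.null(center)) NA_real_ else gh_distance(center, query)
  nh <- if (k >= 3) {
    ncm <- fit_center(subset_rows(lib, nb$index))
    gh_distance(ncm, query)
  } else NA_real_

  structure(list(value = sum(w * preds), per_factor_predictions = preds,
                 weights = w, neighbor_ids = nb$ids,
                 correlations = nb$correlations, gh = gh, nh = nh),
            class = "LocalPrediction")
}

#' Evaluate a k-by-l optimization grid for the LOCAL algorithm
#'
#' Runs [local_predict()] for every validation query at every (k, l)
#' combination and tabulates full prediction diagnostics per cell. The
#' usual design for grape quality traits is k in
#' \{25, 50, 75, 100, 110, 125, 150\} by l in \{14, 15, 16\} (21 cells);
#' the potassium design restricts k to \{25, 50, 75\} (9 cells). The best
#' cell minimizes the bias-corrected prediction error SEP(c) by default.
#'
#' @param library pretreated `SpectraSet` of library (calibration) samples.
#' @param y_library reference values aligned with the library.
#' @param validation pretreated `SpectraSet` of query samples.
#' @param y_validation reference values aligned with the validation rows.
#' @param k_grid,l_grid integer vectors of candidate k and l values.
#' @param cfg a [local_config()] supplying the remaining parameters.
#' @param criterion `"sepc"` (default) or `"sep"` for best-cell selection.
#' @return list with `grid` (data.frame: k, l, n, sep, sepc, bias, r2,
#'   slope, rpd), `best` (the winning row) and `predictions` (matrix,
#'   validation x cells).
#' @export
optimize_local_grid <- function(library, y_library, validation, y_validation,
                                k_grid, l_grid, cfg = local_config(),
                                criterion = c("sepc", "sep")) {
  criterion <- match.arg(criterion)
  if (!length(k_grid) || !length(l_grid)) stop("grids must be non-empty")
  if (length(intersect(library$meta$sample_id, validation$meta$sample_id)))
    stop("validation samples must be disjoint from the library")
  keep_k <- k_grid >= cfg$min_library
  if (!all(keep_k)) {
    warning("skipping k cells below min_library: ",
            paste(k_grid[!keep_k], collapse = ", "))
    k_grid <- k_grid[keep_k]
  }
  cells <- expand.grid(k = sort(k_grid), l = sort(l_grid))
  nv <- n_spectra(validation)
  preds <- matrix(NA_real_, nv, nrow(cells))
  lib_center <- if (n_spectra(library) >= 3) fit_center(library) else NULL
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cc <- local_config(k = cells$k[ci], l_max = cells$l[ci],
                       n_discard = cfg$n_discard,
                       min_library = cfg$min_library,
                       weighting = cfg$weighting, mode = cfg$mode)
    for (i in seq_len(nv)) {
      preds[i, ci] <- local_predict(library, y_library, validation$x[i, ],
                                    cc, center = lib_center)$value
    }
    st <- eval_stats(y_validation, preds[, ci], context = "prediction",
                     sd_ref = stats::sd(y_library, na.rm = TRUE))
    rows[[ci]] <- data.frame(k = cells$k[ci], l = cells$l[ci], n = st$n,
                             sep = st$sep, sepc = st$sepc, bias = st$bias,
                             r2 = st$r2, slope = st$slope, rpd = st$rpd)
  }
  grid <- do.call(rbind, rows)
  best <- grid[which.min(grid[[criterion]]), , drop = FALSE]
  list(grid = grid, best = best, predictions = preds)
}
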
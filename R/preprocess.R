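#' Parse a four-number derivative treatment code
#'
#' Treatment codes follow the WinISI convention "d,g,s1,s2": derivative
#' order, gap (in data points) over which the finite difference is taken,
#' and two running-average smoothing widths (in data points; 1 means no
#' smoothing). The codes used for grape calibrations are "1,5,5,1",
#' "2,5,5,1", "1,10,5,1" and "2,10,5,1". All four numbers are interpreted as
#' data points; on a 2 nm grid one point is 2 nm.
#'
#' @param code character scalar such as `"2,5,5,1"`.
#' @return a `DerivativeSpec`: list with `order`, `gap`, `smooth1`,
#'   `smooth2`.
#' @export
parse_treatment <- function(code) {
  parts <- strsplit(trimws(code), ",", fixed = TRUE)[[1]]
  if (length(parts) != 4)
    stop("treatment code must have four comma-separated integers: ", code)
  v <- suppressWarnings(as.integer(parts))
  if (anyNA(v) || any(v < 0))
    stop("treatment code entries must be nonnegative integers: ", code)
  derivative_spec(v[1], v[2], v[3], v[4])
}

#' Construct a DerivativeSpec
#'
#' @param order derivative order, 0 (none), 1 or 2.
#' @param gap gap in points; must be >= 1 when `order >= 1`.
#' @param smooth1,smooth2 running-mean widths in points (odd, >= 1; 1 = no
#'   smoothing).
#' @return a `DerivativeSpec` list.
#' @export
derivative_spec <- function(order, gap, smooth1 = 1, smooth2 = 1) {
  if (!order %in% 0:2) stop("derivative order must be 0, 1 or 2")
  if (order >= 1 && gap < 1) stop("gap must be >= 1 for derivatives")
  if (smooth1 < 1 || smooth2 < 1) stop("smoothing widths must be >= 1")
  if (smooth1 %% 2 == 0 || smooth2 %% 2 == 0)
    stop("smoothing widths must be odd (centered running mean)")
  structure(list(order = as.integer(order), gap = as.integer(gap),
                 smooth1 = as.integer(smooth1), smooth2 = as.integer(smooth2)),
            class = "DerivativeSpec")
}

#' Construct a PretreatmentSpec
#'
#' Bundles the three pretreatment choices the calibration protocol scans:
#' scatter correction, derivative code, and spectral window. The candidate
#' windows for grape spectra are 380-1650 (Vis+NIR), 780-1650 (NIR incl.
#' very-near IR) and 1100-1650 nm (strict NIR).
#'
#' @param scatter one of `"none"`, `"snv"`, `"snv_detrend"`.
#' @param treatment a `DerivativeSpec` or a code string for
#'   [parse_treatment()].
#' @param window numeric length-2, window bounds in nm, or `NULL` for the
#'   full grid.
#' @return a `PretreatmentSpec` list.
#' @export
pretreatment_spec <- function(scatter = "snv_detrend", treatment = "2,5,5,1",
                              window = c(380, 1650)) {
  scatter <- match.arg(scatter, c("none", "snv", "snv_detrend"))
  if (is.character(treatment)) treatment <- parse_treatment(treatment)
  if (!inherits(treatment, "DerivativeSpec"))
    stop("treatment must be a DerivativeSpec or a code string")
  if (!is.null(window)) {
    window <- as.numeric(window)
    if (length(window) != 2 || window[1] >= window[2])
      stop("window must be c(lo, hi) with lo < hi")
  }
  structure(list(scatter = scatter, derivative = treatment, window = window),
            class = "PretreatmentSpec")
}

#' @export
print.PretreatmentSpec <- function(x, ...) {
  d <- x$derivative
  cat(sprintf("Pretreatment: scatter=%s, derivative=%d,%d,%d,%d, window=%s\n",
              x$scatter, d$order, d$gap, d$smooth1, d$smooth2,
              if (is.null(x$window)) "full"
              else paste(x$window, collapse = "-")))
  invisible(x)
}

#' Standard normal variate and detrend scatter correction
#'
#' SNV centers each spectrum to mean 0 and scales it to unit standard
#' deviation (sample SD, denominator n-1), removing multiplicative scatter
#' and additive baseline offsets. Detrending additionally fits a
#' second-degree polynomial in wavelength to the SNV-corrected spectrum by
#' least squares and subtracts it, removing curvilinear baseline drift.
#'
#' @param values numeric vector, one spectrum (>= 3 points, nonzero SD).
#' @param mode `"snv"` or `"snv_detrend"`.
#' @param wavelengths wavelength grid, needed for detrending (defaults to
#'   the point index, which spans the same quadratic space).
#' @return the corrected numeric vector, same length.
#' @export
snv_detrend <- function(values, mode = c("snv", "snv_detrend"),
                        wavelengths = seq_along(values)) {
  mode <- match.arg(mode)
  if (length(values) < 3) stop("need at least 3 points")
  sdv <- stats::sd(values)
  if (!is.finite(sdv) || sdv == 0) stop("zero-variance spectrum")
  z <- (values - mean(values)) / sdv
  if (mode == "snv_detrend") {
    w <- wavelengths - mean(wavelengths)   # centered for conditioning
    z <- stats::lm.fit(cbind(1, w, w^2), z)$residuals
  }
  z
}

# centered running mean of odd width; drops (width-1)/2 points per side
running_mean <- function(x, width) {
  if (width == 1) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  if (n < width) stop("spectrum too short for smoothing width ", width)
  cs <- cumsum(c(0, x))
  (cs[(width + 1):(n + 1)] - cs[1:(n - width + 1)]) / width
  # result aligns to original indices (h+1):(n-h)
}

#' Gap-segment derivative of one spectrum
#'
#' First derivative: `y_i = x_{i+g} - x_{i-g}`; second derivative:
#' `y_i = x_{i+g} - 2 x_i + x_{i-g}`, with gap `g` in points, followed by
#' centered running-average smoothing of widths `smooth1` then `smooth2`
#' (width 1 is a no-op). Edges are truncated: output is restricted to
#' indices whose full support lies on the grid, so the output grid is
#' shorter by `2*gap + (smooth1-1) + (smooth2-1)` points in total.
#'
#' @param values numeric vector, one spectrum.
#' @param spec a `DerivativeSpec`.
#' @param wavelengths optional grid aligned with `values`.
#' @return list with `values` (transformed) and `wavelengths` (the retained
#'   sub-grid; point indices if no grid was supplied).
#' @export
gap_derivative <- function(values, spec, wavelengths = seq_along(values)) {
  stopifnot(inherits(spec, "DerivativeSpec"))
  n <- length(values)
  if (length(wavelengths) != n) stop("wavelengths must align with values")
  g <- spec$gap
  if (spec$order >= 1) {
    need <- 2 * g + (spec$smooth1 - 1) + (spec$smooth2 - 1) + 1
    if (n < need) stop("spectrum too short for derivative support (need ",
                       need, " points, have ", n, ")")
    idx <- (g + 1):(n - g)
    y <- switch(spec$order,
                values[idx + g] - values[idx - g],                    # 1st
                values[idx + g] - 2 * values[idx] + values[idx - g])  # 2nd
    wl <- wavelengths[idx]
  } else {
    y <- values
    wl <- wavelengths
  }
  for (width in c(spec$smooth1, spec$smooth2)) {
    if (width > 1) {
      h <- (width - 1L) %/% 2L
      y <- running_mean(y, width)
      wl <- wl[(h + 1):(length(wl) - h)]
    }
  }
  list(values = y, wavelengths = wl)
}

#' Apply a full pretreatment to a SpectraSet
#'
#' Pipeline order: slice to the spectral window, then scatter correction
#' (SNV or SNV + detrend, per spectrum), then the gap-segment derivative.
#' Every row is transformed identically and independently.
#'
#' @param s a `SpectraSet`.
#' @param p a `PretreatmentSpec` (or arguments for [pretreatment_spec()] via
#'   `...`).
#' @return the pretreated `SpectraSet` on its (possibly shorter) grid, with
#'   the spec attached as attribute `"pretreatment"`.
#' @export
apply_pretreatment <- function(s, p) {
  stopifnot(inherits(p, "PretreatmentSpec"))
  if (!is.null(p$window)) s <- slice_range(s, p$window[1], p$window[2])
  x <- s$x
  if (p$scatter != "none") {
    x <- t(apply(x, 1, snv_detrend,
                 mode = if (p$scatter == "snv") "snv" else "snv_detrend",
                 wavelengths = s$wavelengths))
  }
  d <- p$derivative
  if (d$order >= 1 || d$smooth1 > 1 || d$smooth2 > 1) {
    first <- gap_derivative(x[1, ], d, s$wavelengths)
    out <- matrix(0.0, nrow(x), length(first$values))
    out[1, ] <- first$values
    if (nrow(x) > 1)
      for (i in 2:nrow(x)) out[i, ] <- gap_derivative(x[i, ], d)$values
    res <- spectra_set(out, first$wavelengths, s$meta, check_step = FALSE)
  } else {
    res <- spectra_set(x, s$wavelengths, s$meta, check_step = FALSE)
  }
  attr(res, "pretreatment") <- p
  res
}
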
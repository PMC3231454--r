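#' NIRS diagnostic statistics for a set of predictions
#'
#' Computes the standard calibration/validation diagnostics from reference
#' values and predictions. With residuals `e = y_pred - y_ref`:
#' \itemize{
#'   \item `bias = mean(e)`
#'   \item `sep = sqrt(sum(e^2) / n)` — standard error of prediction
#'   \item `sepc = sqrt(sum((e - bias)^2) / (n - 1))` — bias-corrected SEP
#'   \item `r2` — squared Pearson correlation of reference and prediction
#'   \item `slope` — least-squares slope of reference regressed on
#'     prediction
#' }
#' These denominators (n for SEP, n-1 for SEP(c)) satisfy the identity
#' `n*sep^2 = (n-1)*sepc^2 + n*bias^2`, the convention under which published
#' (SEP, SEP(c), bias, n) quadruples are mutually consistent; note it allows
#' `sepc > sep` when the bias is small. In `cv` context the same
#' root-mean-square error is reported as `secv`, and `rpd = sd_ref / secv`,
#' `cv_percent = 100 * secv / mean_ref` are filled when the reference
#' summaries are supplied. In `calibration` context
#' `sec = sqrt(RSS / (n - n_factors - 1))`.
#'
#' @param y_ref reference values.
#' @param y_pred predicted values, same length, n >= 2.
#' @param context one of `"prediction"`, `"cv"`, `"calibration"`.
#' @param sd_ref standard deviation of the reference data (for RPD).
#' @param mean_ref mean of the reference data (for CV%).
#' @param n_factors model factor count (for SEC in calibration context).
#' @return an `EvalStats` list: `n`, `bias`, `sep`, `sepc`, `secv`, `sec`,
#'   `r2`, `slope`, `rpd`, `cv_percent`.
#' @export
eval_stats <- function(y_ref, y_pred,
                       context = c("prediction", "cv", "calibration"),
                       sd_ref = NULL, mean_ref = NULL, n_factors = NULL) {
  context <- match.arg(context)
  y_ref <- as.numeric(y_ref); y_pred <- as.numeric(y_pred)
  n <- length(y_ref)
  if (length(y_pred) != n) stop("y_ref and y_pred must have equal length")
  if (n < 2) stop("need at least 2 observations")
  e <- y_pred - y_ref
  bias <- mean(e)
  sep <- sqrt(sum(e^2) / n)
  sepc <- sqrt(sum((e - bias)^2) / (n - 1))
  if (stats::sd(y_pred) == 0) stop("zero-variance predictions (slope undefined)")
  r2 <- stats::cor(y_ref, y_pred)^2
  slope <- stats::cov(y_ref, y_pred) / stats::var(y_pred)
  secv <- if (context == "cv") sep else NA_real_
  sec <- if (context == "calibration") {
    k <- if (is.null(n_factors)) 0 else n_factors
    sqrt(sum(e^2) / max(n - k - 1, 1))
  } else NA_real_
  err_for_ratio <- if (context == "cv") secv else sep
  rpd_val <- if (!is.null(sd_ref) && err_for_ratio > 0)
    sd_ref / err_for_ratio else NA_real_
  cvp <- if (!is.null(mean_ref) && mean_ref != 0)
    100 * err_for_ratio / mean_ref else NA_real_
  structure(list(n = n, bias = bias, sep = sep, sepc = sepc, secv = secv,
                 sec = sec, r2 = r2, slope = slope, rpd = rpd_val,
                 cv_percent = cvp),
            class = "EvalStats")
}

#' @export
print.EvalStats <- function(x, ...) {
  cat(sprintf("EvalStats (n=%d): bias=%.4g SEP=%.4g SEP(c)=%.4g r2=%.3f slope=%.3f\n",
              x$n, x$bias, x$sep, x$sepc, x$r2, x$slope))
  invisible(x)
}

#' Ratio of performance to deviation (RPD)
#'
#' `sd_ref / secv`: the reference-data standard deviation over the
#' cross-validation (or prediction) error. Values above 3 conventionally
#' indicate excellent quantitative ability; below about 1.5 the model only
#' separates high from low.
#'
#' @param sd_ref standard deviation of the reference data.
#' @param secv standard error of cross-validation (or prediction), > 0.
#' @return the unitless ratio.
#' @export
rpd <- function(sd_ref, secv) {
  if (secv <= 0) stop("secv must be > 0")
  sd_ref / secv
}

#' Coefficient of variation of a calibration error
#'
#' `100 * secv / mean_ref`, the error as a percentage of the mean reference
#' value.
#'
#' @param secv standard error of cross-validation (or prediction).
#' @param mean_ref mean of the reference data, nonzero.
#' @return percentage.
#' @export
cv_percent <- function(secv, mean_ref) {
  if (mean_ref == 0) stop("mean_ref must be nonzero")
  100 * secv / mean_ref
}

#' Relative improvement between two model statistics
#'
#' For error statistics (SEP, SEP(c)), the reduction relative to the
#' reference model: `100 * (reference - improved) / reference`. For r2-type
#' statistics, the gain relative to the improved model:
#' `100 * (improved - reference) / improved`.
#'
#' @param reference_stat the baseline model's statistic.
#' @param improved_stat the challenger model's statistic.
#' @param kind `"error_reduction"` or `"r2_gain"`.
#' @return percentage (positive = challenger better).
#' @export
improvement_percent <- function(reference_stat, improved_stat,
                                kind = c("error_reduction", "r2_gain")) {
  kind <- match.arg(kind)
  if (kind == "error_reduction") {
    if (reference_stat == 0) stop("zero reference statistic")
    100 * (reference_stat - improved_stat) / reference_stat
  } else {
    if (improved_stat == 0) stop("zero improved statistic")
    100 * (improved_stat - reference_stat) / improved_stat
  }
}

#' Round half-up to a number of decimals
#'
#' Report tables round half-up (so 2.405 prints as 2.41), matching the
#' usual chemometric reporting style rather than banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
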
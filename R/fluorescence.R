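#' Paired ROI/background fluorescence trace
#'
#' @param roi mean ROI fluorescence series (AU).
#' @param background mean background fluorescence series (AU), same length.
#' @param sample_rate sampling rate (Hz), > 0; default 0.5 Hz as in the
#'   imaging protocol.
#' @return Object of class `"fluorescence_trace"`.
#' @export
fluorescence_trace <- function(roi, background, sample_rate = 0.5) {
  if (length(roi) != length(background))
    stop("'roi' and 'background' must have equal length", call. = FALSE)
  if (sample_rate <= 0) stop("'sample_rate' must be > 0 Hz", call. = FALSE)
  if (any(!is.finite(roi)) || any(!is.finite(background)))
    stop("fluorescence series must be finite (no NaN)", call. = FALSE)
  structure(list(sample_rate = sample_rate,
                 roi = as.numeric(roi), background = as.numeric(background)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d samples at %g Hz (%.4g s)\n",
              length(x$roi), x$sample_rate, length(x$roi) / x$sample_rate))
  invisible(x)
}

#' Subtract background fluorescence from the ROI
#'
#' @param trace a [fluorescence_trace()].
#' @return Numeric series `roi - background` (AU).
#' @export
background_subtract <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  trace$roi - trace$background
}

#' Linear photobleach baseline of a fluorescence series
#'
#' Ordinary least-squares regression of the entire series on time; the
#' fitted line serves as the photobleaching baseline.
#'
#' @param series fluorescence values (AU).
#' @param sample_rate sampling rate (Hz).
#' @return List with `slope` (AU/s), `intercept` (AU) and `baseline` (the
#'   fitted line at each sample).
#' @export
linear_baseline <- function(series, sample_rate) {
  if (length(series) < 3) stop("need at least 3 samples", call. = FALSE)
  stopifnot(sample_rate > 0)
  t <- (seq_along(series) - 1) / sample_rate
  fit <- stats::lm.fit(cbind(1, t), series)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       baseline = unname(fit$fitted.values))
}

#' Photobleach-corrected fractional fluorescence change
#'
#' Computes the background-subtracted ROI signal `F_corr`, its linear
#' regression baseline `F0(t)` (photobleach correction), and
#' \eqn{\Delta F/F(t) = (F_{corr}(t) - F_0(t)) / F_0(t)}. With
#' `mode = "subtract"` the baseline is only subtracted, not divided out
#' (signal stays in AU).
#'
#' @param trace a [fluorescence_trace()].
#' @param mode `"dff"` (default) or `"subtract"`.
#' @return Object of class `"dff_trace"`: list with `sample_rate`, `dff`,
#'   `baseline_slope` (AU/s), `baseline_intercept` (AU).
#' @export
compute_dff <- function(trace, mode = c("dff", "subtract")) {
  mode <- match.arg(mode)
  f_corr <- background_subtract(trace)
  bl <- linear_baseline(f_corr, trace$sample_rate)
  if (mode == "dff") {
    bad <- which(bl$baseline <= 0)
    if (length(bad))
      stop(sprintf("nonpositive regression baseline at sample %d: cannot form dF/F",
                   bad[1]), call. = FALSE)
    dff <- (f_corr - bl$baseline) / bl$baseline
  } else {
    dff <- f_corr - bl$baseline
  }
  structure(list(sample_rate = trace$sample_rate, dff = dff,
                 baseline_slope = bl$slope, baseline_intercept = bl$intercept,
                 mode = mode),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dF/F trace (%s): %d samples at %g Hz; baseline slope %.4g AU/s\n",
              x$mode, length(x$dff), x$sample_rate, x$baseline_slope))
  invisible(x)
}

#' Cumulative dF/F (total variation)
#'
#' Sums the absolute sample-to-sample differences of a dF/F series,
#' \eqn{\sum_t |x_{t+1} - x_t|}: a time-integrated measure of calcium
#' activity that is insensitive to the temporal pattern of transients.
#'
#' @param dff a [compute_dff()] result, or a plain numeric series.
#' @return Dimensionless scalar total variation.
#' @examples
#' cumulative_dff(c(0, 0.2, 0.1, 0.4))  # 0.6
#' @export
cumulative_dff <- function(dff) {
  x <- if (inherits(dff, "dff_trace")) dff$dff else as.numeric(dff)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' Full GCaMP trace pipeline
#'
#' Background subtraction, linear photobleach baseline, dF/F and the
#' cumulative dF/F statistic, composed deterministically. With
#' `statistic = "raw"` the total variation is taken over the
#' background-subtracted ROI series itself (no detrending or division),
#' the alternative reading of summing absolute ROI differences.
#'
#' @inheritParams compute_dff
#' @param statistic `"dff"` (default; total variation of the dF/F series)
#'   or `"raw"`.
#' @return List with `dff` (the [compute_dff()] result) and `cumulative`.
#' @export
trace_pipeline <- function(trace, mode = c("dff", "subtract"),
                           statistic = c("dff", "raw")) {
  statistic <- match.arg(statistic)
  d <- compute_dff(trace, mode = mode)
  cum <- if (statistic == "dff") cumulative_dff(d)
         else cumulative_dff(background_subtract(trace))
  list(dff = d, cumulative = cum)
}
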
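#' Window-current curve
#'
#' The steady-state window current arises where activation and inactivation
#' curves overlap; it is modeled as their product
#' \eqn{w(V) = m_\infty(V) \cdot h_\infty(V)}.
#'
#' @param act activation-sense [boltzmann_params()].
#' @param inact inactivation-sense [boltzmann_params()].
#' @param v_grid voltages (mV) at which to evaluate.
#' @return List with `voltages` and `w` (fractions in (0, 1)).
#' @export
window_curve <- function(act, inact, v_grid) {
  stopifnot(inherits(act, "boltzmann_params"), inherits(inact, "boltzmann_params"))
  if (act$sense != "activation" || inact$sense != "inactivation")
    stop("'act' must be activation-sense and 'inact' inactivation-sense",
         call. = FALSE)
  list(voltages = as.numeric(v_grid),
       w = boltzmann(v_grid, act) * boltzmann(v_grid, inact))
}

#' Window-current peak and range metrics
#'
#' Locates the peak of the window curve (coarse grid scan refined by
#' golden-section/parabolic search) and the outermost voltages at which the
#' window exceeds `threshold_frac` of its peak (found by root bracketing;
#' the log of the window curve is concave, so each side has a unique
#' crossing). The width of the window range is `v_high - v_low`.
#'
#' @inheritParams window_curve
#' @param threshold_frac fraction of the peak defining the window range,
#'   in (0, 1); default 0.1.
#' @return Object of class `"window_metrics"`: list with `v_peak`, `w_peak`,
#'   `v_low`, `v_high`, `width`, `threshold_frac`.
#' @examples
#' window_metrics(boltzmann_params(-40, 5, "activation"),
#'                boltzmann_params(-60, 5, "inactivation"))
#' @export
window_metrics <- function(act, inact, threshold_frac = 0.1) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  wfun <- function(v) window_curve(act, inact, v)$w
  span <- 25 * max(act$k, inact$k)
  lo <- min(act$v_half, inact$v_half) - span
  hi <- max(act$v_half, inact$v_half) + span
  grid <- seq(lo, hi, length.out = 2001)
  i0 <- which.max(wfun(grid))
  bracket <- grid[c(max(i0 - 1, 1), min(i0 + 1, length(grid)))]
  opt <- stats::optimize(wfun, interval = bracket, maximum = TRUE,
                         tol = 1e-10)
  v_peak <- opt$maximum
  w_peak <- opt$objective
  target <- threshold_frac * w_peak
  cross <- function(side) {
    # march outward until below target, then bisect
    v_out <- v_peak + side * span
    while (wfun(v_out) >= target) v_out <- v_out + side * span
    stats::uniroot(function(v) wfun(v) - target,
                   lower = min(v_out, v_peak), upper = max(v_out, v_peak),
                   tol = 1e-10)$root
  }
  v_low <- cross(-1)
  v_high <- cross(+1)
  structure(list(v_peak = v_peak, w_peak = w_peak,
                 v_low = v_low, v_high = v_high,
                 width = v_high - v_low, threshold_frac = threshold_frac),
            class = "window_metrics")
}

#' @export
print.window_metrics <- function(x, ...) {
  cat(sprintf("Window current: peak %.4g at %.4g mV\n", x$w_peak, x$v_peak))
  cat(sprintf("  range (>= %.3g of peak): %.4g to %.4g mV (width %.4g mV)\n",
              x$threshold_frac, x$v_low, x$v_high, x$width))
  invisible(x)
}
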
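#' Boltzmann steady-state gating parameters
#'
#' Half-voltage and slope factor of a steady-state gating curve. With
#' `sense = "activation"` the curve is the increasing sigmoid
#' \eqn{m_\infty(V) = 1/(1+\exp((V_{1/2}-V)/k))}; with
#' `sense = "inactivation"` the decreasing sigmoid
#' \eqn{h_\infty(V) = 1/(1+\exp((V-V_{1/2})/k))}.
#'
#' @param v_half half-activation / half-inactivation potential (mV).
#' @param k slope factor (mV), > 0.
#' @param sense `"activation"` or `"inactivation"`.
#' @return Object of class `"boltzmann_params"`.
#' @examples
#' wt_act <- boltzmann_params(-37.14, 5, "activation")
#' boltzmann(-37.14, wt_act)  # 0.5 at the half-voltage
#' @export
boltzmann_params <- function(v_half, k, sense = c("activation", "inactivation")) {
  sense <- match.arg(sense)
  stopifnot(is.numeric(v_half), length(v_half) == 1L, is.finite(v_half),
            is.numeric(k), length(k) == 1L)
  if (!is.finite(k) || k <= 0)
    stop("slope factor 'k' must be > 0 mV", call. = FALSE)
  structure(list(v_half = v_half, k = k, sense = sense),
            class = "boltzmann_params")
}

#' @export
print.boltzmann_params <- function(x, ...) {
  cat(sprintf("Boltzmann %s curve: V1/2 = %.4g mV, k = %.4g mV\n",
              x$sense, x$v_half, x$k))
  invisible(x)
}

#' Evaluate a steady-state Boltzmann gating curve
#'
#' @param v membrane potentials (mV), vectorised.
#' @param params a [boltzmann_params()] object.
#' @return Gating fractions in (0, 1).
#' @export
boltzmann <- function(v, params) {
  stopifnot(inherits(params, "boltzmann_params"))
  u <- if (params$sense == "activation") (params$v_half - v) / params$k
       else (v - params$v_half) / params$k
  stats::plogis(-u)
}

#' Normalized conductance curve
#'
#' Pairs voltages with (normalized) conductances. With `normalize = TRUE`
#' the values are rescaled so the maximum is 1.
#'
#' @param voltages test voltages (mV).
#' @param g conductances (arbitrary or normalized units), >= 0.
#' @param normalize rescale so `max(g) == 1`?
#' @return Object of class `"conductance_curve"`: list with `voltages`, `g`.
#' @export
conductance_curve <- function(voltages, g, normalize = TRUE) {
  stopifnot(length(voltages) == length(g), length(g) >= 1)
  if (any(g < 0)) stop("conductances must be non-negative", call. = FALSE)
  if (normalize) {
    m <- max(g)
    if (m <= 0) stop("cannot normalize an all-zero conductance curve", call. = FALSE)
    g <- g / m
  }
  structure(list(voltages = as.numeric(voltages), g = as.numeric(g)),
            class = "conductance_curve")
}

#' @export
print.conductance_curve <- function(x, ...) {
  cat(sprintf("Conductance curve: %d voltages from %g to %g mV, max g = %.4g\n",
              length(x$voltages), min(x$voltages), max(x$voltages), max(x$g)))
  invisible(x)
}

#' Fit a Boltzmann sigmoid to a steady-state gating curve
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of the
#' activation- or inactivation-sense Boltzmann to normalized conductance
#' (or availability) data, as performed by standard sigmoidal-fit tools.
#' 95% confidence intervals are asymptotic (estimate +/- 1.96 SE from the
#' least-squares covariance).
#'
#' @param curve a [conductance_curve()] object, or anything with `voltages`
#'   and `g` components; at least 4 points.
#' @param sense `"activation"` or `"inactivation"`.
#' @param init optional starting [boltzmann_params()]; a data-driven start
#'   is used when absent.
#' @return Object of class `"boltzmann_fit"` with components `params`
#'   (fitted [boltzmann_params()]), `ci95` (2 x 2 matrix), `rss`,
#'   `converged`, `n`, and the underlying `nls` object in `fit`.
#' @examples
#' act <- boltzmann_params(-44.69, 4, "activation")
#' crv <- conductance_curve(seq(-80, 10, 10), boltzmann(seq(-80, 10, 10), act),
#'                          normalize = FALSE)
#' coef(fit_boltzmann(crv, "activation"))
#' @export
fit_boltzmann <- function(curve, sense = c("activation", "inactivation"),
                          init = NULL) {
  sense <- match.arg(sense)
  v <- curve$voltages
  g <- curve$g
  if (length(v) < 4) stop("need at least 4 points to fit", call. = FALSE)
  if (any(g < 0) || any(g > 1 + 0.25))
    stop("conductance values must lie in [0, 1] (small overshoot tolerated)",
         call. = FALSE)
  sgn <- if (sense == "activation") 1 else -1
  if (is.null(init)) {
    # midpoint from the crossing of 0.5, slope from the data spread
    ord <- order(v)
    v_half0 <- stats::approx(g[ord], v[ord], xout = 0.5, ties = mean)$y
    if (is.na(v_half0)) v_half0 <- stats::median(v)
    k0 <- diff(range(v)) / 10
  } else {
    stopifnot(inherits(init, "boltzmann_params"))
    v_half0 <- init$v_half
    k0 <- init$k
  }
  dat <- data.frame(v = v, g = g)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ 1 / (1 + exp(sgn * (v_half - v) / k)),
      data = dat,
      start = list(v_half = v_half0, k = k0),
      lower = c(v_half = min(v) - 200, k = 1e-3),
      upper = c(v_half = max(v) + 200, k = 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, ci95 = NULL, rss = NA_real_,
                          converged = FALSE, n = length(v), sense = sense,
                          fit = NULL),
                     class = "boltzmann_fit"))
  }
  est <- stats::coef(fit)
  # a fit driven onto the slope-factor bounds indicates sense mismatch or
  # degenerate data; flag rather than error
  at_bound <- est[["k"]] <= 1e-3 * 1.01 || est[["k"]] >= 1e3 * 0.99
  ci <- tryCatch({
    se <- sqrt(diag(stats::vcov(fit)))
    cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  }, error = function(e) NULL)
  structure(list(
    params = boltzmann_params(est[["v_half"]], est[["k"]], sense),
    ci95 = ci,
    rss = sum(stats::resid(fit)^2),
    converged = fit$convInfo$isConv && !at_bound,
    n = length(v),
    sense = sense,
    fit = fit), class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  if (is.null(object$params)) return(c(v_half = NA_real_, k = NA_real_))
  c(v_half = object$params$v_half, k = object$params$k)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit (n = %d points)%s\n", x$sense, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$params)) {
    ci <- x$ci95
    fmt <- function(i) if (is.null(ci)) "" else
      sprintf("  (95%% CI %.4g to %.4g)", ci[i, 1], ci[i, 2])
    cat(sprintf("  V1/2 = %.4g mV%s\n", x$params$v_half, fmt(1)))
    cat(sprintf("  k    = %.4g mV%s\n", x$params$k, fmt(2)))
    cat(sprintf("  RSS  = %.4g\n", x$rss))
  }
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) print(summary(object$fit))
  invisible(object)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$params)) stop("fit did not converge; no parameters")
  v <- if (is.null(newdata)) object$fit$m$getEnv()$v
       else if (is.list(newdata)) newdata$v else newdata
  boltzmann(v, object$params)
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::resid(object$fit)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  env <- x$fit$m$getEnv()
  graphics::plot(env$v, env$g, xlab = "Voltage (mV)",
                 ylab = "Normalized conductance", ...)
  vv <- seq(min(env$v), max(env$v), length.out = 200)
  graphics::lines(vv, boltzmann(vv, x$params))
  invisible(x)
}
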
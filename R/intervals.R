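#' Parameters of the two-state egg-laying interval model
#'
#' The egg-laying system switches between an active state, in which eggs are
#' laid in clusters, and a long-lived inactive state.  The marginal
#' distribution of inter-event intervals implied by this two-state process is
#' a two-exponential mixture with cumulative distribution
#' \deqn{F(x) = 1 - \left[A e^{-a x} + B e^{-p b x}\right],}
#' where \eqn{A = p(a-b)/(a-pb)} and \eqn{B = a(1-p)/(a-pb)} (so \eqn{A+B=1}
#' identically).  \code{a} is the fast (intra-cluster) rate and \code{p b}
#' the slow (inter-cluster) rate, both in events per minute.
#'
#' @param p mixing/state parameter, strictly inside (0, 1).
#' @param a fast rate constant (1/min), > 0.
#' @param b slow rate scale (1/min), > 0; the slow mixture rate is `p * b`.
#' @return An object of class `"interval_params"`: a named list with
#'   elements `p`, `a`, `b`.
#' @examples
#' interval_params(p = 0.5, a = 1, b = 0.1)
#' @export
interval_params <- function(p, a, b) {
  stopifnot(is.numeric(p), is.numeric(a), is.numeric(b),
            length(p) == 1L, length(a) == 1L, length(b) == 1L)
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive rate", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("'b' must be a positive rate", call. = FALSE)
  if (a == p * b)
    stop("degenerate parameters: a equals p*b (mixture weights undefined)",
         call. = FALSE)
  structure(list(p = p, a = a, b = b), class = "interval_params")
}

#' @export
print.interval_params <- function(x, ...) {
  cat("Egg-laying interval model parameters\n")
  cat(sprintf("  p = %.6g   a = %.6g /min   b = %.6g /min\n", x$p, x$a, x$b))
  w <- mixture_weights(x)
  cat(sprintf("  mixture: weight %.4g on rate %.6g /min, weight %.4g on rate %.6g /min\n",
              w$A, x$a, w$B, x$p * x$b))
  invisible(x)
}

# A on the fast-rate (a) exponential, B on the slow (p*b); A + B = 1.
mixture_weights <- function(params) {
  d <- params$a - params$p * params$b
  list(A = params$p * (params$a - params$b) / d,
       B = params$a * (1 - params$p) / d)
}

as_interval_params <- function(x) {
  if (inherits(x, "interval_params")) return(x)
  if (is.list(x) || (is.numeric(x) && !is.null(names(x)))) {
    x <- as.list(x)
    return(interval_params(x$p, x$a, x$b))
  }
  stop("cannot interpret 'params' as interval model parameters", call. = FALSE)
}

#' Interval-model cumulative distribution function
#'
#' Evaluates the two-exponential mixture CDF of inter-egg-laying intervals.
#'
#' @param x interval lengths in minutes, each >= 0 (vectorised).
#' @param params an [interval_params()] object.
#' @return Probabilities in \[0, 1\], same length as `x`.
#' @examples
#' interval_cdf(1, interval_params(0.5, 1, 0.1))  # 0.32509
#' @seealso [interval_pdf()], [fit_intervals()]
#' @export
interval_cdf <- function(x, params) {
  params <- as_interval_params(params)
  if (any(!is.finite(x)) || any(x < 0))
    stop("interval lengths must be finite and >= 0", call. = FALSE)
  w <- mixture_weights(params)
  1 - (w$A * exp(-params$a * x) + w$B * exp(-params$p * params$b * x))
}

#' Interval-model probability density function
#'
#' Derivative of [interval_cdf()]:
#' \eqn{f(x) = A a e^{-a x} + B p b e^{-p b x}}.
#'
#' @inheritParams interval_cdf
#' @return Densities (1/min), same length as `x`.
#' @export
interval_pdf <- function(x, params) {
  params <- as_interval_params(params)
  if (any(!is.finite(x)) || any(x < 0))
    stop("interval lengths must be finite and >= 0", call. = FALSE)
  w <- mixture_weights(params)
  s <- params$p * params$b
  w$A * params$a * exp(-params$a * x) + w$B * s * exp(-s * x)
}

#' Interval-model quantile function
#'
#' Numerical inverse of [interval_cdf()] by monotone root-finding.
#'
#' @param q probabilities in \[0, 1).
#' @inheritParams interval_cdf
#' @return Interval lengths (minutes) such that `interval_cdf(x) == q`.
#' @export
interval_quantile <- function(q, params) {
  params <- as_interval_params(params)
  stopifnot(all(q >= 0), all(q < 1))
  upper <- 1
  vapply(q, function(qi) {
    if (qi == 0) return(0)
    while (interval_cdf(upper, params) < qi) upper <<- upper * 2
    stats::uniroot(function(x) interval_cdf(x, params) - qi,
                   lower = 0, upper = upper, tol = 1e-12)$root
  }, numeric(1))
}

#' Fast and slow time constants of the interval model
#'
#' The reciprocal rates of the two mixture components: `tau_fast = 1/a` is
#' the intra-cluster timescale of the active state, `tau_slow = 1/(p*b)` the
#' quiescence timescale separating clusters.
#'
#' @inheritParams interval_cdf
#' @return Named numeric vector `c(tau_fast =, tau_slow =)` in minutes.
#' @examples
#' time_constants(interval_params(0.5, 1, 0.1))  # 1 and 20 minutes
#' @export
time_constants <- function(params) {
  params <- as_interval_params(params)
  tf <- 1 / params$a
  ts <- 1 / (params$p * params$b)
  if (tf >= ts)
    warning("tau_fast >= tau_slow: component labels are not identifiable; ",
            "consider canonicalising with a > p*b")
  c(tau_fast = tf, tau_slow = ts)
}

#' Mean inter-event interval under the model
#'
#' \eqn{E[X] = A/a + B/(pb)} for the two-exponential mixture.
#'
#' @inheritParams interval_cdf
#' @return Mean interval in minutes.
#' @examples
#' mean_interval(interval_params(0.5, 1, 0.1))  # 11.0 min
#' @export
mean_interval <- function(params) {
  params <- as_interval_params(params)
  w <- mixture_weights(params)
  w$A / params$a + w$B / (params$p * params$b)
}

# Re-express an (A-weight, fast-rate, slow-rate) mixture in (p, a, b) form
# with a > p*b, so the fast component always carries label `a`.
canonicalise_params <- function(params) {
  params <- as_interval_params(params)
  if (params$a > params$p * params$b) return(params)
  w <- mixture_weights(params)
  r_fast <- max(params$a, params$p * params$b)
  r_slow <- min(params$a, params$p * params$b)
  A_fast <- if (params$a >= params$p * params$b) w$A else w$B
  p_new <- A_fast + r_slow * (1 - A_fast) / r_fast
  tryCatch(interval_params(p = p_new, a = r_fast, b = r_slow / p_new),
           error = function(e) {
             warning("could not canonicalise parameters (improper mixture); ",
                     "returning them unchanged")
             params
           })
}
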
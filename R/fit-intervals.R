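#' Fit the two-state interval model to observed intervals
#'
#' Nonlinear least squares of the two-exponential mixture CDF against the
#' empirical cumulative probability of the sample: the sorted intervals are
#' paired with Hazen plotting positions \eqn{(i - 0.5)/n} and the CDF is
#' fitted by Levenberg-Marquardt with box constraints keeping the
#' parameters in their valid region (`p` in (1e-4, 1-1e-4), rates in
#' (1e-6, 1e3) per minute). When no starting values are given, the sample
#' is split at its median and each half fitted as a single exponential to
#' initialise the fast and slow rates. After fitting, the components are
#' relabelled if needed so the fast rate carries the label `a`
#' (`a > p*b`). Confidence intervals are asymptotic (estimate +/- 1.96 SE).
#'
#' @param intervals positive inter-event intervals in minutes (at least
#'   10), or an `egg_timeline` whose successive event differences are used.
#' @param init optional starting [interval_params()].
#' @return Object of class `"interval_fit"`: list with `params` (fitted
#'   [interval_params()]), `ci95` (3 x 2 matrix on the (p, a, b) scale),
#'   `rss`, `converged`, `n`, `intervals`, and the underlying `nls` object
#'   in `fit`.
#' @examples
#' x <- sample_intervals(interval_params(0.5, 1, 0.1), 500, seed = 1)
#' fit <- fit_intervals(x)
#' coef(fit)
#' time_constants(fit$params)
#' @export
fit_intervals <- function(intervals, init = NULL) {
  if (inherits(intervals, "egg_timeline"))
    intervals <- diff(intervals$event_times)
  intervals <- as.numeric(intervals)
  if (length(intervals) < 10)
    stop("need at least 10 intervals to fit", call. = FALSE)
  if (any(intervals <= 0) || any(!is.finite(intervals)))
    stop("intervals must be finite and > 0", call. = FALSE)
  x <- sort(intervals)
  n <- length(x)
  pp <- (seq_len(n) - 0.5) / n          # Hazen plotting positions
  if (is.null(init)) {
    med <- stats::median(x)
    fast0 <- 1 / mean(x[x <= med])
    slow0 <- 1 / mean(x[x > med])
    p0 <- 0.5
    b0 <- slow0 / p0
    a0 <- max(fast0, 1.5 * p0 * b0)     # keep the fast label on a
    init <- list(p = p0, a = a0, b = b0)
  } else {
    init <- as_interval_params(init)
  }
  dat <- data.frame(x = x, pp = pp)
  cdf_expr <- function(x, p, a, b) {
    d <- a - p * b
    1 - (p * (a - b) / d * exp(-a * x) + a * (1 - p) / d * exp(-p * b * x))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      pp ~ cdf_expr(x, p, a, b),
      data = dat,
      start = list(p = init$p, a = init$a, b = init$b),
      lower = c(p = 1e-4, a = 1e-6, b = 1e-6),
      upper = c(p = 1 - 1e-4, a = 1e3, b = 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, ci95 = NULL, rss = NA_real_,
                          converged = FALSE, n = n, intervals = x, fit = NULL),
                     class = "interval_fit"))
  }
  est <- stats::coef(fit)
  params <- tryCatch(
    canonicalise_params(interval_params(est[["p"]], est[["a"]], est[["b"]])),
    error = function(e) NULL)
  ci <- tryCatch({
    se <- sqrt(diag(stats::vcov(fit)))
    cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  }, error = function(e) NULL)
  structure(list(
    params = params,
    ci95 = ci,
    rss = sum(stats::resid(fit)^2),
    converged = isTRUE(fit$convInfo$isConv) && !is.null(params),
    n = n,
    intervals = x,
    fit = fit), class = "interval_fit")
}

#' @export
coef.interval_fit <- function(object, ...) {
  if (is.null(object$params)) return(c(p = NA_real_, a = NA_real_, b = NA_real_))
  c(p = object$params$p, a = object$params$a, b = object$params$b)
}

#' @export
print.interval_fit <- function(x, ...) {
  cat(sprintf("Two-state egg-laying interval model fit (n = %d intervals)%s\n",
              x$n, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$params)) {
    est <- coef(x)
    ci <- x$ci95
    for (i in seq_along(est)) {
      ci_txt <- if (is.null(ci)) "" else
        sprintf("  (95%% CI %.4g to %.4g)", ci[i, 1], ci[i, 2])
      cat(sprintf("  %s = %.4g%s\n", names(est)[i], est[i], ci_txt))
    }
    tc <- time_constants(x$params)
    cat(sprintf("  tau_fast = %.4g min, tau_slow = %.4g min\n",
                tc[["tau_fast"]], tc[["tau_slow"]]))
    cat(sprintf("  RSS = %.4g\n", x$rss))
  }
  invisible(x)
}

#' @export
summary.interval_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$params)) {
    cat(sprintf("  mean interval = %.4g min\n", mean_interval(object$params)))
  }
  invisible(object)
}

#' @export
predict.interval_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$params)) stop("fit did not converge; no parameters")
  x <- if (is.null(newdata)) object$intervals
       else if (is.list(newdata)) newdata$x else newdata
  interval_cdf(x, object$params)
}

#' @export
residuals.interval_fit <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::resid(object$fit)
}

#' @export
simulate.interval_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$params)) stop("fit did not converge; no parameters")
  sample_intervals(object$params, n = nsim, seed = seed)
}

#' @export
plot.interval_fit <- function(x, ...) {
  n <- x$n
  graphics::plot(x$intervals, (seq_len(n) - 0.5) / n, log = "x",
                 xlab = "Interval (min)", ylab = "Cumulative probability", ...)
  if (!is.null(x$params)) {
    xx <- exp(seq(log(min(x$intervals)), log(max(x$intervals)),
                  length.out = 300))
    graphics::lines(xx, interval_cdf(xx, x$params))
  }
  invisible(x)
}
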
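# All generators take an integer `seed` and are bit-reproducible under it.
# The global RNG state is restored on exit so simulation calls do not
# perturb the caller's random stream.
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Sample inter-egg-laying intervals from the two-state model
#'
#' Draws i.i.d. intervals from the two-exponential mixture: with weight
#' \eqn{A = p(a-b)/(a-pb)} an exponential of rate `a` (intra-cluster), with
#' weight \eqn{1-A} an exponential of rate `p*b` (inter-cluster quiescence).
#' The empirical CDF of the sample converges to [interval_cdf()].
#'
#' @param params an [interval_params()] object; additionally the mixture
#'   weight must lie in \[0, 1\] (requires `a >= b`), otherwise the CDF is
#'   not a probability mixture and cannot be sampled componentwise.
#' @param n number of intervals, >= 1.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG state.
#' @return Numeric vector of `n` positive intervals (minutes).
#' @examples
#' x <- sample_intervals(interval_params(0.5, 1, 0.1), n = 1000, seed = 1)
#' mean(x)  # close to mean_interval(...) = 11.0 min
#' @export
sample_intervals <- function(params, n, seed = NULL) {
  params <- as_interval_params(params)
  stopifnot(length(n) == 1L, n >= 1)
  w <- mixture_weights(params)
  if (w$A < 0 || w$A > 1)
    stop("mixture weight A = p(a-b)/(a-p*b) outside [0, 1]; ",
         "these parameters do not define a sampleable mixture (need a >= b)",
         call. = FALSE)
  with_preserved_seed(seed, {
    fast <- stats::runif(n) < w$A
    x <- numeric(n)
    x[fast] <- stats::rexp(sum(fast), rate = params$a)
    x[!fast] <- stats::rexp(sum(!fast), rate = params$p * params$b)
    x
  })
}

#' Simulate an egg-laying event timeline
#'
#' Cumulative sums of sampled intervals, truncated at `duration`; a renewal
#' process with the two-exponential interval law.
#'
#' @inheritParams sample_intervals
#' @param duration observation length in minutes, > 0.
#' @return Object of class `"egg_timeline"`: list with `event_times`
#'   (strictly increasing minutes within \[0, duration\]) and `duration`.
#' @export
simulate_timeline <- function(params, duration, seed = NULL) {
  params <- as_interval_params(params)
  stopifnot(length(duration) == 1L, duration > 0)
  with_preserved_seed(seed, {
    times <- numeric(0)
    t_now <- 0
    # draw in blocks to avoid per-event sampler calls
    repeat {
      block <- cumsum(sample_intervals(params, 64L, seed = NULL)) + t_now
      times <- c(times, block[block <= duration])
      t_now <- block[length(block)]
      if (t_now > duration) break
    }
    structure(list(event_times = times, duration = duration),
              class = "egg_timeline")
  })
}

#' @export
print.egg_timeline <- function(x, ...) {
  cat(sprintf("Egg-laying timeline: %d events over %.4g min\n",
              length(x$event_times), x$duration))
  invisible(x)
}

# Shared noisy-Boltzmann curve generator; `sense` picks the monotone sense.
simulate_gating_curves <- function(params, voltages, noise_sd, n_cells, seed) {
  stopifnot(inherits(params, "boltzmann_params"))
  if (length(voltages) == 0) stop("voltage list must be non-empty", call. = FALSE)
  stopifnot(noise_sd >= 0, n_cells >= 1)
  clean <- boltzmann(voltages, params)
  with_preserved_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      g <- clean + stats::rnorm(length(voltages), 0, noise_sd)
      conductance_curve(voltages, pmax(g, 0), normalize = FALSE)
    })
  })
}

#' Simulate noisy steady-state activation curves
#'
#' Per cell, \eqn{g(V) = m_\infty(V) + N(0, \sigma)} clipped to be
#' non-negative, with \eqn{m_\infty} the increasing Boltzmann. Emulates the
#' per-oocyte normalized chord-conductance data entering a steady-state
#' activation analysis.
#'
#' @param act activation-sense [boltzmann_params()].
#' @param voltages test voltages (mV).
#' @param noise_sd Gaussian noise SD on the normalized conductance scale.
#' @param n_cells number of cells (curves).
#' @param seed integer seed.
#' @return List of `n_cells` [conductance_curve()] objects.
#' @export
simulate_peak_conductance <- function(act, voltages, noise_sd = 0.02,
                                      n_cells = 10, seed = NULL) {
  if (act$sense != "activation")
    stop("'act' must have sense = \"activation\"", call. = FALSE)
  simulate_gating_curves(act, voltages, noise_sd, n_cells, seed)
}

#' Simulate noisy steady-state inactivation (availability) curves
#'
#' As [simulate_peak_conductance()] but with the decreasing Boltzmann sense:
#' availability approaches 1 at very negative prepulses.
#'
#' @param inact inactivation-sense [boltzmann_params()].
#' @param prepulses prepulse voltages (mV).
#' @inheritParams simulate_peak_conductance
#' @return List of `n_cells` [conductance_curve()] objects.
#' @export
simulate_inactivation_curve <- function(inact, prepulses, noise_sd = 0.02,
                                        n_cells = 7, seed = NULL) {
  if (inact$sense != "inactivation")
    stop("'inact' must have sense = \"inactivation\"", call. = FALSE)
  simulate_gating_curves(inact, prepulses, noise_sd, n_cells, seed)
}

#' Simulate a GCaMP fluorescence trace
#'
#' ROI signal = resting fluorescence `f0` + linear photobleach drift +
#' exponential-decay calcium transients + Gaussian noise; background channel
#' = constant `bg` + Gaussian noise. Defaults follow the imaging protocol of
#' 0.5 Hz sampling for 15 minutes (450 frames).
#'
#' @param transient_times onset times of transients (s), within
#'   \[0, duration\].
#' @param amplitude transient amplitude (AU); recycled over transients.
#' @param decay_tau exponential decay time constant (s), > 0.
#' @param bleach_slope linear drift (AU/s), typically negative.
#' @param f0 resting ROI fluorescence (AU).
#' @param bg mean background fluorescence (AU).
#' @param noise_sd Gaussian noise SD (AU) applied to both channels.
#' @param duration recording length (s).
#' @param rate sampling rate (Hz), > 0.
#' @param seed integer seed.
#' @return A [fluorescence_trace()] object.
#' @export
simulate_fluorescence <- function(transient_times = numeric(0), amplitude = 50,
                                  decay_tau = 4, bleach_slope = -0.02,
                                  f0 = 200, bg = 50, noise_sd = 0,
                                  duration = 900, rate = 0.5, seed = NULL) {
  stopifnot(rate > 0, decay_tau > 0, duration > 0)
  if (length(transient_times) &&
      (any(transient_times < 0) || any(transient_times > duration)))
    stop("transient times must lie within [0, duration]", call. = FALSE)
  t <- seq(0, by = 1 / rate, length.out = floor(duration * rate))
  roi <- f0 + bleach_slope * t
  amplitude <- rep_len(amplitude, length(transient_times))
  for (i in seq_along(transient_times)) {
    on <- t >= transient_times[i]
    roi[on] <- roi[on] + amplitude[i] * exp(-(t[on] - transient_times[i]) / decay_tau)
  }
  background <- rep(bg, length(t))
  with_preserved_seed(seed, {
    if (noise_sd > 0) {
      roi <- roi + stats::rnorm(length(t), 0, noise_sd)
      background <- background + stats::rnorm(length(t), 0, noise_sd)
    }
    fluorescence_trace(roi, background, sample_rate = rate)
  })
}

#' Sample an embryo-stage distribution
#'
#' Multinomial draw of `n` embryos over the seven ordinal developmental
#' stage categories.
#'
#' @param probs seven non-negative probabilities summing to 1 (tolerance
#'   1e-8 after checking; renormalised internally).
#' @param n total embryo count, >= 0.
#' @param seed integer seed.
#' @return A [stage_distribution()] object.
#' @export
sample_stages <- function(probs, n, seed = NULL) {
  if (length(probs) != 7L)
    stop("'probs' must have exactly 7 categories", call. = FALSE)
  if (any(probs < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-6)
    stop("'probs' must sum to 1", call. = FALSE)
  stopifnot(n >= 0)
  counts <- if (n == 0) rep(0L, 7L) else
    with_preserved_seed(seed, as.integer(stats::rmultinom(1, n, probs)))
  stage_distribution(counts)
}
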
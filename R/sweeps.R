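#' Voltage-step protocol
#'
#' Describes a two-electrode voltage-clamp step protocol. The activation
#' protocol holds at `holding` and steps to each test voltage; the
#' inactivation protocol applies a long conditioning prepulse at each
#' voltage in `steps`, then a fixed test step to `test_voltage`, and the
#' recorded sweep is the test-step current. Defaults are standard
#' low-voltage-activated protocols: activation from -90 mV with 150-ms
#' steps -80..+10 mV in 10-mV increments; inactivation with 1-s prepulses
#' -100..-30 mV in 5-mV increments and a -30 mV test step.
#'
#' @param kind `"activation"` or `"inactivation"`.
#' @param holding holding potential (mV).
#' @param steps test-step voltages (activation) or prepulse voltages
#'   (inactivation), mV; non-empty.
#' @param step_duration duration of the recorded step (ms), > 0.
#' @param prepulse_duration conditioning prepulse length (ms), inactivation
#'   only, > 0.
#' @param test_voltage test-step voltage (mV), inactivation only.
#' @param sample_interval sampling interval (ms), > 0.
#' @return Object of class `"step_protocol"`.
#' @export
step_protocol <- function(kind = c("activation", "inactivation"),
                          holding = -90,
                          steps = if (kind == "activation") seq(-80, 10, 10)
                                  else seq(-100, -30, 5),
                          step_duration = 150,
                          prepulse_duration = 1000,
                          test_voltage = -30,
                          sample_interval = 0.5) {
  kind <- match.arg(kind)
  if (length(steps) == 0) stop("'steps' must be non-empty", call. = FALSE)
  stopifnot(step_duration > 0, sample_interval > 0, prepulse_duration > 0)
  structure(list(kind = kind, holding = holding, steps = as.numeric(steps),
                 step_duration = step_duration,
                 prepulse_duration = if (kind == "inactivation") prepulse_duration else NA_real_,
                 test_voltage = if (kind == "inactivation") test_voltage else NA_real_,
                 sample_interval = sample_interval),
            class = "step_protocol")
}

#' Kinetic channel model for sweep simulation
#'
#' A minimal Hodgkin-Huxley-style description `I = scale * m * h * drive(V)`
#' with first-order relaxation of activation `m` (time constant `tau_m`) and
#' inactivation `h` (`tau_h`) toward their steady-state Boltzmann values.
#' Default time constants are order-of-magnitude T-type kinetics.
#'
#' @param scale current per unit drive (µA per drive unit).
#' @param act activation-sense [boltzmann_params()].
#' @param inact inactivation-sense [boltzmann_params()].
#' @param tau_m,tau_h activation / inactivation time constants (ms), > 0.
#' @param ghk a [ghk_settings()] object supplying the driving term.
#' @return Object of class `"channel_model"`.
#' @export
channel_model <- function(scale = 1,
                          act = boltzmann_params(-37.14, 5, "activation"),
                          inact = boltzmann_params(-58.18, 5, "inactivation"),
                          tau_m = 5, tau_h = 30,
                          ghk = ghk_settings()) {
  stopifnot(inherits(act, "boltzmann_params"), act$sense == "activation",
            inherits(inact, "boltzmann_params"), inact$sense == "inactivation",
            inherits(ghk, "ghk_settings"))
  if (tau_m <= 0 || tau_h <= 0)
    stop("time constants must be > 0 ms", call. = FALSE)
  structure(list(scale = scale, act = act, inact = inact,
                 tau_m = tau_m, tau_h = tau_h, ghk = ghk),
            class = "channel_model")
}

# m(t)/h(t): first-order relaxation from x0 toward xinf
relax <- function(t, x0, xinf, tau) xinf + (x0 - xinf) * exp(-t / tau)

#' Simulate voltage-clamp current sweeps
#'
#' Per step voltage V the recorded current is
#' \eqn{I(t) = scale \cdot m(t;V) \cdot h(t;V) \cdot drive(V) + noise},
#' with m and h relaxing first-order from their pre-step values to steady
#' state. For activation protocols the pre-step state is the holding-state
#' steady state; for inactivation protocols `h` enters the test step from
#' its value at the end of the conditioning prepulse and the drive is
#' evaluated at the test voltage.
#'
#' @param model a [channel_model()].
#' @param protocol a [step_protocol()].
#' @param noise_sd Gaussian current noise SD (µA).
#' @param seed integer seed.
#' @return Object of class `"sweep_set"`: list with `protocol`, `time`
#'   (ms from step onset) and `currents` (one numeric series per step,
#'   columns named `V_<voltage>`).
#' @export
simulate_sweeps <- function(model, protocol, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "channel_model"), inherits(protocol, "step_protocol"))
  t <- seq(0, protocol$step_duration, by = protocol$sample_interval)
  m_hold <- boltzmann(protocol$holding, model$act)
  h_hold <- boltzmann(protocol$holding, model$inact)
  sweeps <- vapply(protocol$steps, function(v_step) {
    if (protocol$kind == "activation") {
      v_test <- v_step
      h0 <- h_hold
    } else {
      v_test <- protocol$test_voltage
      # h relaxes at the prepulse voltage for the prepulse duration
      h0 <- relax(protocol$prepulse_duration, h_hold,
                  boltzmann(v_step, model$inact), model$tau_h)
    }
    m <- relax(t, m_hold, boltzmann(v_test, model$act), model$tau_m)
    h <- relax(t, h0, boltzmann(v_test, model$inact), model$tau_h)
    model$scale * m * h * ghk_drive(v_test, model$ghk)
  }, numeric(length(t)))
  colnames(sweeps) <- paste0("V_", protocol$steps)
  with_preserved_seed(seed, {
    if (noise_sd > 0)
      sweeps <- sweeps + stats::rnorm(length(sweeps), 0, noise_sd)
    structure(list(protocol = protocol, time = t, currents = sweeps),
              class = "sweep_set")
  })
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set (%s): %d steps x %d samples, dt = %g ms\n",
              x$protocol$kind, ncol(x$currents), nrow(x$currents),
              x$protocol$sample_interval))
  invisible(x)
}

#' Extract peak currents from a sweep set
#'
#' Per sweep, the signed value of largest magnitude after discarding the
#' first `blank_ms` of the step (capacitive-transient blanking). Inward
#' currents are negative.
#'
#' @param sweeps a [sweep_set()][simulate_sweeps] object.
#' @param blank_ms initial blanking window (ms), must be shorter than the
#'   step.
#' @return List with `voltages` (the per-sweep step/prepulse voltages) and
#'   `peaks` (signed peak currents, µA).
#' @export
extract_peaks <- function(sweeps, blank_ms = 2) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (blank_ms >= sweeps$protocol$step_duration)
    stop("'blank_ms' must be smaller than the step duration", call. = FALSE)
  keep <- sweeps$time >= blank_ms
  peaks <- apply(sweeps$currents[keep, , drop = FALSE], 2, function(i) {
    if (all(i == 0)) {
      warning("all-flat sweep: peak reported as 0")
      return(0)
    }
    i[which.max(abs(i))]
  })
  list(voltages = sweeps$protocol$steps, peaks = unname(peaks))
}

#' Chord-conductance curve from peak currents
#'
#' Divides each peak current by the Goldman-Hodgkin-Katz driving term at its
#' test voltage and normalizes the result to a maximum of 1, yielding the
#' steady-state activation curve shape.
#'
#' @param voltages test voltages (mV).
#' @param peaks signed peak currents (µA).
#' @param ghk a [ghk_settings()] object.
#' @return A normalized [conductance_curve()].
#' @export
chord_conductance_curve <- function(voltages, peaks, ghk = ghk_settings()) {
  stopifnot(length(voltages) == length(peaks))
  drive <- ghk_drive(voltages, ghk)
  # a step at (or numerically at) the reversal potential has no driving force
  drive_scale <- abs(ghk$permeability_scale) * abs(ghk$z) * .FARADAY *
    (ghk$c_in + ghk$c_out)
  bad <- abs(drive) < 1e-9 * drive_scale
  if (any(bad))
    stop(sprintf("test voltage at the reversal potential (step %s mV): chord conductance undefined",
                 paste(voltages[bad], collapse = ", ")), call. = FALSE)
  conductance_curve(voltages, pmax(peaks / drive, 0), normalize = TRUE)
}

#' Oocyte leak-current quality control
#'
#' An oocyte passes if the magnitude of its holding (leak) current at the
#' holding potential is strictly below the threshold magnitude; the default
#' threshold is -0.1 µA at -90 mV with the inward-negative convention. The
#' boundary itself fails (strict inequality).
#'
#' @param holding_current measured holding current (µA), vectorised.
#' @param threshold leak threshold (µA), default -0.1.
#' @return Logical: `TRUE` = pass.
#' @examples
#' qc_leak(c(-0.05, -0.1, -0.2))  # TRUE FALSE FALSE
#' @export
qc_leak <- function(holding_current, threshold = -0.1) {
  abs(holding_current) < abs(threshold)
}
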
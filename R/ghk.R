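# Physical constants (SI)
.FARADAY <- 96485.33212    # C/mol
.GAS_CONST <- 8.31446262   # J/(mol K)

#' Goldman-Hodgkin-Katz settings
#'
#' Ion valence, temperature and concentrations for the constant-field flux
#' expression used to convert peak currents into chord conductances.
#' Defaults describe divalent barium as the charge carrier with a 10 mM
#' external bath; internal activity is nominally low. Because chord
#' conductances are normalized per cell, only the shape of the drive versus
#' voltage matters, not its absolute scale.
#'
#' @param z ion valence (nonzero integer; 2 for Ba2+).
#' @param temperature absolute temperature (K).
#' @param c_in internal concentration (mM), > 0.
#' @param c_out external concentration (mM), > 0.
#' @param permeability_scale arbitrary multiplicative permeability.
#' @return Object of class `"ghk_settings"`.
#' @export
ghk_settings <- function(z = 2, temperature = 295, c_in = 0.1, c_out = 10,
                         permeability_scale = 1) {
  stopifnot(length(z) == 1L, length(temperature) == 1L)
  if (z == 0 || z != round(z)) stop("valence 'z' must be a nonzero integer", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  if (c_in <= 0 || c_out <= 0) stop("concentrations must be > 0", call. = FALSE)
  structure(list(z = as.integer(z), temperature = temperature,
                 c_in = c_in, c_out = c_out,
                 permeability_scale = permeability_scale),
            class = "ghk_settings")
}

#' @export
print.ghk_settings <- function(x, ...) {
  cat(sprintf("GHK settings: z = %+d, T = %g K, [in] = %g mM, [out] = %g mM\n",
              x$z, x$temperature, x$c_in, x$c_out))
  cat(sprintf("  reversal potential: %.4g mV\n", reversal_potential(x)))
  invisible(x)
}

#' GHK driving term (current per unit permeability)
#'
#' The constant-field flux expression
#' \deqn{I(V) = P z^2 F^2 V / (RT) \cdot
#'       \frac{c_{in} - c_{out} e^{-u}}{1 - e^{-u}}, \quad u = zFV/RT,}
#' evaluated continuously across V = 0 via a series expansion of
#' \eqn{u/(1-e^{-u})} for |u| < 1e-4 (the exact expression is 0/0 there);
#' the limit value at V = 0 is \eqn{zFP(c_{in}-c_{out})}.
#'
#' @param v membrane potentials (mV), vectorised.
#' @param ghk a [ghk_settings()] object.
#' @return Driving term in arbitrary consistent units (sign convention:
#'   inward flux of a cation with `c_out > c_in` is negative).
#' @examples
#' g <- ghk_settings()            # Ba2+, 100:1 outward gradient
#' ghk_drive(reversal_potential(g), g)  # 0 at the Nernst potential
#' @export
ghk_drive <- function(v, ghk = ghk_settings()) {
  stopifnot(inherits(ghk, "ghk_settings"))
  u <- ghk$z * .FARADAY * (v / 1000) / (.GAS_CONST * ghk$temperature)
  # g(u) = u / (1 - exp(-u)); 3-term Taylor splice near u = 0
  small <- abs(u) < 1e-4
  gu <- numeric(length(u))
  gu[small] <- 1 + u[small] / 2 + u[small]^2 / 12
  gu[!small] <- u[!small] / (1 - exp(-u[!small]))
  ghk$permeability_scale * ghk$z * .FARADAY *
    (ghk$c_in - ghk$c_out * exp(-u)) * gu
}

#' Reversal potential of the GHK drive
#'
#' The Nernst potential \eqn{(RT/zF)\ln(c_{out}/c_{in})}, the unique root of
#' [ghk_drive()].
#'
#' @inheritParams ghk_drive
#' @return Reversal potential in mV.
#' @examples
#' reversal_potential(ghk_settings(z = 2, temperature = 295,
#'                                 c_in = 0.1, c_out = 10))  # +58.5 mV
#' @export
reversal_potential <- function(ghk = ghk_settings()) {
  stopifnot(inherits(ghk, "ghk_settings"))
  1000 * .GAS_CONST * ghk$temperature / (ghk$z * .FARADAY) *
    log(ghk$c_out / ghk$c_in)
}
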
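# Package-wide unit system: pN, nm, s, K; energies in pN nm.

#' Boltzmann constant in package units
#'
#' `1.380649e-23` J/K expressed in pN nm / K.
#'
#' @format Length-one numeric.
#' @export
kB <- 1.380649e-2

#' Thermal energy scale
#'
#' Computes k_B T in pN nm, the energy scale used throughout the
#' worm-like-chain and Bell-model expressions. At the standard measurement
#' temperature of 20 degC (293.15 K) this is about 4.047 pN nm.
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal energy in pN nm.
#' @examples
#' kBT(293.15)
#' @export
kBT <- function(temperature = 293.15) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    abort("`temperature` must be positive and finite (kelvin).")
  }
  kB * temperature
}

# Default monomer length (nm): saccharide ring (0.483) plus the carboxyl
# group engaged in the bond (0.192).
l_mono_default <- function() 0.483 + 0.192
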
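# Unit contract, used throughout: time ms, voltage mV, current nA,
# conductance density mS cm^-2, membrane area cm^2, intracellular Ca nM,
# extracellular Ca mM. All conversion constants live here.

# Physical constants (SI)
.GAS_CONSTANT <- 8.314      # J K^-1 mol^-1
.FARADAY <- 96485           # C mol^-1
.CA_VALENCE <- 2

# 1 mS * 1 mV = 1 uA = 1000 nA
.NA_PER_MS_MV <- 1000

# nM per mM
.NM_PER_MM <- 1e6

#' Membrane area of a spherical neuron
#'
#' Area is taken as the sphere surface pi * d^2, which is how conductance and
#' capacitance densities (per cm^2) scale to whole-cell totals.
#'
#' @param diameter_um cell diameter in micrometres.
#' @return area in cm^2.
#' @examples
#' membrane_area(10) # ~3.14e-6 cm^2
#' @export
membrane_area <- function(diameter_um) {
  stopifnot(is.numeric(diameter_um), all(diameter_um > 0))
  d_cm <- diameter_um * 1e-4
  pi * d_cm^2
}

#' Calcium Nernst potential
#'
#' Equilibrium potential of a divalent calcium channel,
#' \eqn{E = (RT / zF) \log(Ca_e / Ca_i)} with z = 2, in mV. The intracellular
#' concentration is given in nM and the extracellular one in mM, matching the
#' scales on which the model operates.
#'
#' @param Ca_i_nM intracellular calcium, nM (> 0).
#' @param Ca_e_mM extracellular calcium, mM (> 0).
#' @param temperature_K absolute temperature, K.
#' @return potential in mV; decreasing in `Ca_i_nM`.
#' @examples
#' nernst_potential(20, 2, 294) # about +145.8 mV
#' @export
nernst_potential <- function(Ca_i_nM, Ca_e_mM, temperature_K = 294) {
  if (any(!is.finite(Ca_i_nM)) || any(Ca_i_nM <= 0)) {
    stop("Ca_i_nM must be positive and finite")
  }
  if (any(!is.finite(Ca_e_mM)) || any(Ca_e_mM <= 0)) {
    stop("Ca_e_mM must be positive and finite")
  }
  stopifnot(temperature_K > 0)
  rt_zf <- .GAS_CONSTANT * temperature_K / (.CA_VALENCE * .FARADAY) # volts
  1000 * rt_zf * log(Ca_e_mM * .NM_PER_MM / Ca_i_nM)
}
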
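# Single-compartment non-spiking neuron: passive RC membrane, one
# non-inactivating voltage-gated Ca channel, and an intracellular Ca pool
# that drives graded transmitter release downstream.

#' Neuron parameter set
#'
#' All neurons in the model are physiologically identical; the defaults are
#' the model's standard values. Densities are per cm^2 and scale to whole-cell
#' totals through the spherical membrane area.
#'
#' The calcium inflow factor `B` converts channel current to the rate of
#' concentration change inside a restricted cytoplasmic volume. Its nominal
#' value (1000) is kept as published; `B_scale` (nM ms^-1 nA^-1 per unit of B)
#' sets the effective inflow rate `B * B_scale` in the model's nM/ms/nA
#' contract, and was calibrated once by bisection on the single-oscillator
#' tonic-drive scenario so that excitor calcium traverses the synaptic release
#' midpoint and the oscillator cycles (see the methods vignette).
#'
#' @param diameter cell diameter, um.
#' @param C_m specific membrane capacitance, uF cm^-2.
#' @param g_leak leak conductance density, mS cm^-2.
#' @param V_leak_eq leak equilibrium potential, mV.
#' @param g_Ca_max maximal Ca-channel conductance density, mS cm^-2.
#' @param V_mid half-activation voltage of the Ca channel, mV.
#' @param S_Ca activation slope sensitivity, mV.
#' @param tau_m activation time constant, ms.
#' @param B calcium inflow factor (nominal units mM s^-1 nA^-1).
#' @param B_scale effective-inflow conversion, nM ms^-1 nA^-1 per unit B.
#' @param tau_Ca_clr calcium clearance time constant, ms.
#' @param Ca_i_min minimum intracellular calcium, nM.
#' @param Ca_i_init initial intracellular calcium, nM.
#' @param Ca_e extracellular calcium, mM.
#' @param temperature absolute temperature, K.
#' @return an object of class `neuron_parameters`.
#' @examples
#' p <- neuron_parameters()
#' p$g_leak
#' @export
neuron_parameters <- function(diameter = 10,
                              C_m = 1,
                              g_leak = 0.35,
                              V_leak_eq = -60,
                              g_Ca_max = 0.08,
                              V_mid = -40,
                              S_Ca = 7.5,
                              tau_m = 50,
                              B = 1000,
                              B_scale = .default_B_scale,
                              tau_Ca_clr = 400,
                              Ca_i_min = 0.1,
                              Ca_i_init = 20,
                              Ca_e = 2,
                              temperature = 294) {
  p <- list(diameter = diameter, C_m = C_m, g_leak = g_leak,
            V_leak_eq = V_leak_eq, g_Ca_max = g_Ca_max, V_mid = V_mid,
            S_Ca = S_Ca, tau_m = tau_m, B = B, B_scale = B_scale,
            tau_Ca_clr = tau_Ca_clr, Ca_i_min = Ca_i_min,
            Ca_i_init = Ca_i_init, Ca_e = Ca_e, temperature = temperature)
  for (f in c("diameter", "C_m", "g_leak", "tau_m", "tau_Ca_clr", "S_Ca",
              "Ca_e", "temperature", "Ca_i_min", "B_scale")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop(sprintf("neuron parameter '%s' must be a single positive number", f))
    }
  }
  if (p$g_Ca_max < 0 || p$B < 0) stop("g_Ca_max and B must be non-negative")
  if (p$Ca_i_init < p$Ca_i_min) stop("Ca_i_init must be >= Ca_i_min")
  p$area <- membrane_area(diameter)
  class(p) <- "neuron_parameters"
  p
}

# Effective calcium inflow conversion. Calibrated once by bisection against
# the single-HO tonic scenario (oscillation requires B_scale <= 0.013) and
# full-chain metachronal propagation (requires B_scale >= 0.012); see the
# methods vignette. Gives B_eff = B * B_scale = 12 nM ms^-1 nA^-1 at the
# nominal B = 1000.
.default_B_scale <- 0.012

#' @export
print.neuron_parameters <- function(x, ...) {
  cat("Neuron parameters (single-compartment, non-spiking)\n")
  cat(sprintf("  diameter %g um (area %.4g cm^2), C_m %g uF/cm^2\n",
              x$diameter, x$area, x$C_m))
  cat(sprintf("  leak: %g mS/cm^2 -> %g mV; Ca: g_max %g mS/cm^2, V_mid %g mV, S %g mV, tau_m %g ms\n",
              x$g_leak, x$V_leak_eq, x$g_Ca_max, x$V_mid, x$S_Ca, x$tau_m))
  cat(sprintf("  Ca pool: B %g x scale %g, tau_clr %g ms, min %g nM, init %g nM; Ca_e %g mM, T %g K\n",
              x$B, x$B_scale, x$tau_Ca_clr, x$Ca_i_min, x$Ca_i_init,
              x$Ca_e, x$temperature))
  invisible(x)
}

#' Initial neuron state
#'
#' Rest-consistent initial conditions: membrane potential at the leak
#' equilibrium, Ca gate at its steady state for that voltage, calcium at its
#' stated initial value, and the calcium equilibrium potential from the
#' Nernst relation.
#'
#' @param params a [neuron_parameters()] object.
#' @return list with `V_m`, `m`, `Ca_i`, `E_Ca`.
#' @export
initial_neuron_state <- function(params = neuron_parameters()) {
  V <- params$V_leak_eq
  list(V_m = V,
       m = steady_state_activation(V, params$V_mid, params$S_Ca),
       Ca_i = params$Ca_i_init,
       E_Ca = nernst_potential(params$Ca_i_init, params$Ca_e,
                               params$temperature))
}

#' Steady-state Ca-channel activation
#'
#' Standard logistic activation curve,
#' \eqn{m_\infty = 1 / (1 + e^{(V_{mid} - V_m)/S_{Ca}})}.
#'
#' @param V_m membrane potential, mV.
#' @param V_mid half-activation voltage, mV.
#' @param S_Ca slope sensitivity, mV (> 0).
#' @return activation fraction in (0, 1).
#' @export
steady_state_activation <- function(V_m, V_mid = -40, S_Ca = 7.5) {
  stopifnot(S_Ca > 0)
  1 / (1 + exp((V_mid - V_m) / S_Ca))
}

#' One exponential-Euler step of gate activation
#'
#' Relaxes `m` toward `m_inf` with fixed time constant `tau_m`:
#' `m' = m_inf + (m - m_inf) * exp(-dt / tau_m)`.
#'
#' @param m current activation in \[0, 1\].
#' @param m_inf steady-state target.
#' @param tau_m time constant, ms.
#' @param dt step, ms (> 0).
#' @return updated activation, between `m` and `m_inf`.
#' @export
step_activation <- function(m, m_inf, tau_m = 50, dt = 1) {
  stopifnot(dt > 0, tau_m > 0)
  m_inf + (m - m_inf) * exp(-dt / tau_m)
}

#' Ohmic channel current
#'
#' Current through a conductance-density channel scaled by a control factor
#' and the membrane area, `I = control * g_density * area * (V_m - E_eq)`,
#' in nA with the outward-positive sign convention.
#'
#' @param g_max_density maximal conductance density, mS cm^-2.
#' @param control gating factor in \[0, 1\].
#' @param area membrane area, cm^2.
#' @param V_m membrane potential, mV.
#' @param E_eq channel equilibrium potential, mV.
#' @return current in nA (positive outward).
#' @examples
#' # leak of the default neuron, 10 mV above reversal: about +0.011 nA
#' channel_current(0.35, 1, membrane_area(10), -50, -60)
#' @export
channel_current <- function(g_max_density, control, area, V_m, E_eq) {
  stopifnot(all(control >= 0), all(control <= 1))
  control * g_max_density * area * (V_m - E_eq) * .NA_PER_MS_MV
}

#' One exponential-Euler step of intracellular calcium
#'
#' Integrates `dCa/dt = inflow - (Ca - Ca_min)/tau` where inflow (nM/ms) is
#' `B * B_scale * max(0, -I_Ca)`: inward Ca current (negative under the
#' outward-positive convention) raises the concentration; outward current does
#' not deplete it below the clearance path. The result is floored at
#' `Ca_i_min`.
#'
#' @param Ca_i current concentration, nM.
#' @param I_Ca calcium-channel current, nA (negative = inward).
#' @param B nominal inflow factor.
#' @param tau_Ca_clr clearance time constant, ms.
#' @param Ca_i_min floor concentration, nM.
#' @param dt step, ms.
#' @param B_scale effective-inflow conversion (see [neuron_parameters()]).
#' @return updated concentration, nM.
#' @export
step_calcium <- function(Ca_i, I_Ca, B = 1000, tau_Ca_clr = 400,
                         Ca_i_min = 0.1, dt = 1, B_scale = .default_B_scale) {
  stopifnot(dt > 0, tau_Ca_clr > 0)
  inflow <- B * B_scale * pmax(0, -I_Ca)          # nM / ms
  Ca_inf <- Ca_i_min + inflow * tau_Ca_clr
  out <- Ca_inf + (Ca_i - Ca_inf) * exp(-dt / tau_Ca_clr)
  pmax(out, Ca_i_min)
}

#' One exponential-Euler step of the membrane potential
#'
#' Integrates the current-balance equation
#' `C_m * area * dV/dt + sum(I_x) - I_stim = 0` over one step with all
#' conductances held at their step values: V relaxes toward the
#' conductance-weighted reversal plus `I_stim / g_total` with time constant
#' `C_m * area / g_total`.
#'
#' Extra conductances (synaptic, optogenetic) are passed as whole-cell
#' conductances in mS paired with reversal potentials in mV.
#'
#' @param V_m membrane potential at step start, mV.
#' @param m Ca-gate activation to use for this step.
#' @param E_Ca calcium equilibrium potential, mV.
#' @param params a [neuron_parameters()] object.
#' @param g_extra numeric vector of additional whole-cell conductances, mS.
#' @param E_extra reversal potentials matching `g_extra`, mV.
#' @param I_stim injected current, nA.
#' @param dt step, ms.
#' @return updated membrane potential, mV.
#' @export
step_membrane_potential <- function(V_m, m, E_Ca, params = neuron_parameters(),
                                    g_extra = numeric(), E_extra = numeric(),
                                    I_stim = 0, dt = 1) {
  stopifnot(dt > 0, length(g_extra) == length(E_extra), all(g_extra >= 0))
  a <- params$area
  g_leak <- params$g_leak * a                  # mS
  g_Ca <- m * params$g_Ca_max * a
  g_tot <- g_leak + g_Ca + sum(g_extra)
  gE <- g_leak * params$V_leak_eq + g_Ca * E_Ca + sum(g_extra * E_extra)
  V_inf <- (gE + I_stim / .NA_PER_MS_MV) / g_tot
  tau_V <- params$C_m * a / g_tot              # uF / mS = ms
  V_inf + (V_m - V_inf) * exp(-dt / tau_V)
}
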
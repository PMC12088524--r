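# Graded, calcium-dependent synaptic transmission: release rate is a sigmoid
# of presynaptic intracellular Ca, cleft transmitter integrates release vs
# first-order clearance, and the postsynaptic conductance control factor is an
# upper-half sigmoid of the cleft concentration. Each directed connection
# owns an independent cleft state.

#' Synapse parameter set
#'
#' Defaults are the model's standard values: reversal -10 mV (excitatory) /
#' -70 mV (inhibitory); maximum release rate 80 except 20 for the
#' excitatory synapses mediating bilateral (midline) coordination; release
#' midpoint 185 nM (excitatory) / 200 nM (inhibitory) presynaptic Ca (the
#' assignment under which both the hemisegmental oscillator and chain-wide
#' wave propagation function; see the methods vignette); slope 15 nM;
#' transmitter clearance 250 ms; binding sensitivity 0.5; maximal
#' conductance density 1 mS cm^-2; gain 1 except 2 on the inhibitory outputs
#' of detector neurons.
#'
#' @param polarity "excitatory" or "inhibitory".
#' @param V_syn_eq reversal potential, mV (default by polarity).
#' @param r_max maximum release rate, ms^-1.
#' @param Ca_i_mid presynaptic Ca at half-maximal release, nM (default by
#'   polarity).
#' @param S_r release slope sensitivity, nM.
#' @param tau_T_clr transmitter clearance time constant, ms.
#' @param S_bind receptor binding sensitivity (nominal transmitter units).
#' @param g_syn_max maximal postsynaptic conductance density, mS cm^-2.
#' @param gain connection gain multiplier on the postsynaptic conductance.
#' @param r_unit release-rate unit conversion applied when a network is
#'   compiled: the effective per-ms release rate is `r_max * r_unit`. The
#'   default (1e-3) reads the nominal rates as per-second, which places the
#'   cleft-transmitter scale (`r_max * r_unit * tau_T_clr` = 20) on the order
#'   of the receptor binding sensitivity so that the release midpoint governs
#'   the synapse's operating range (see the methods vignette).
#' @return an object of class `synapse_parameters`.
#' @examples
#' synapse_parameters("inhibitory", gain = 2)
#' @export
synapse_parameters <- function(polarity = c("excitatory", "inhibitory"),
                               V_syn_eq = NULL,
                               r_max = 80,
                               Ca_i_mid = NULL,
                               S_r = 15,
                               tau_T_clr = 250,
                               S_bind = 0.5,
                               g_syn_max = 1,
                               gain = 1,
                               r_unit = 1e-3) {
  polarity <- match.arg(polarity)
  if (is.null(V_syn_eq)) V_syn_eq <- if (polarity == "excitatory") -10 else -70
  if (is.null(Ca_i_mid)) Ca_i_mid <- if (polarity == "excitatory") 185 else 200
  p <- list(polarity = polarity, V_syn_eq = V_syn_eq, r_max = r_max,
            Ca_i_mid = Ca_i_mid, S_r = S_r, tau_T_clr = tau_T_clr,
            S_bind = S_bind, g_syn_max = g_syn_max, gain = gain,
            r_unit = r_unit)
  for (f in c("r_max", "S_r", "tau_T_clr", "S_bind", "g_syn_max", "gain",
              "r_unit")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop(sprintf("synapse parameter '%s' must be a single positive number", f))
    }
  }
  class(p) <- "synapse_parameters"
  p
}

#' @export
print.synapse_parameters <- function(x, ...) {
  cat(sprintf(
    "Graded %s synapse: E %g mV, r_max %g/ms, Ca_mid %g nM, S_r %g nM,\n  tau_T %g ms, S_bind %g, g_max %g mS/cm^2, gain %g\n",
    x$polarity, x$V_syn_eq, x$r_max, x$Ca_i_mid, x$S_r, x$tau_T_clr,
    x$S_bind, x$g_syn_max, x$gain))
  invisible(x)
}

#' Optogenetic chloride channel
#'
#' A fixed-conductance anion channel placed in a cell to emulate a light-gated
#' chloride channel (GtACR1): normally completely blocked, it conducts toward
#' -70 mV only during scheduled unblock ("light") windows.
#'
#' @param g_opto_Cl conductance density, mS cm^-2 (0 disables).
#' @param E_opto reversal potential, mV.
#' @return an object of class `opto_channel`.
#' @export
opto_channel <- function(g_opto_Cl = 0.2, E_opto = -70) {
  stopifnot(is.numeric(g_opto_Cl), g_opto_Cl >= 0)
  structure(list(g_opto_Cl = g_opto_Cl, E_opto = E_opto),
            class = "opto_channel")
}

#' Graded release rate
#'
#' Sigmoid of presynaptic intracellular calcium:
#' `r_max / (1 + exp((Ca_i_mid - Ca_i_pre)/S_r))`.
#'
#' @param Ca_i_pre presynaptic calcium, nM (>= 0).
#' @param r_max maximum release rate, ms^-1.
#' @param Ca_i_mid half-maximal-release calcium, nM.
#' @param S_r slope sensitivity, nM.
#' @return release rate in (0, r_max), per ms.
#' @export
release_rate <- function(Ca_i_pre, r_max = 80, Ca_i_mid = 200, S_r = 15) {
  stopifnot(all(Ca_i_pre >= 0), S_r > 0, r_max > 0)
  r_max / (1 + exp((Ca_i_mid - Ca_i_pre) / S_r))
}

#' One exponential-Euler step of cleft transmitter
#'
#' Integrates `dT/dt = rate - T/tau_T_clr`; at a constant rate the steady
#' state is `rate * tau_T_clr`.
#'
#' @param T_cleft nominal cleft transmitter concentration (>= 0).
#' @param rate release rate, per ms.
#' @param tau_T_clr clearance time constant, ms.
#' @param dt step, ms.
#' @return updated transmitter concentration (never negative).
#' @export
step_transmitter <- function(T_cleft, rate, tau_T_clr = 250, dt = 1) {
  stopifnot(dt > 0, tau_T_clr > 0, all(T_cleft >= 0), all(rate >= 0))
  T_inf <- rate * tau_T_clr
  pmax(0, T_inf + (T_cleft - T_inf) * exp(-dt / tau_T_clr))
}

#' Postsynaptic receptor gate
#'
#' Upper-half sigmoid of the nominal transmitter concentration:
#' `m_syn = 2 / (1 + exp(-T/S_bind)) - 1`, zero at T = 0 and saturating
#' toward 1.
#'
#' @param T_cleft nominal transmitter concentration (>= 0).
#' @param S_bind binding sensitivity.
#' @return conductance control factor in \[0, 1).
#' @export
receptor_gate <- function(T_cleft, S_bind = 0.5) {
  if (any(T_cleft < 0)) stop("transmitter concentration must be >= 0")
  stopifnot(S_bind > 0)
  2 / (1 + exp(-T_cleft / S_bind)) - 1
}

#' Postsynaptic current of a graded synapse
#'
#' `I = gain * m_syn * g_syn_max * area * (V_post - V_syn_eq)` in nA,
#' outward-positive. The gain multiplies the postsynaptic conductance after
#' gating, so gain 2 exactly doubles the current at fixed state.
#'
#' @param m_syn conductance control factor in \[0, 1).
#' @param g_syn_max maximal conductance density, mS cm^-2.
#' @param gain connection gain multiplier.
#' @param post_area postsynaptic membrane area, cm^2.
#' @param V_post postsynaptic potential, mV.
#' @param V_syn_eq synaptic reversal potential, mV.
#' @return current in nA.
#' @export
synaptic_current <- function(m_syn, g_syn_max = 1, gain = 1,
                             post_area = membrane_area(10),
                             V_post, V_syn_eq) {
  stopifnot(all(m_syn >= 0), all(m_syn < 1), gain > 0)
  gain * m_syn * g_syn_max * post_area * (V_post - V_syn_eq) * .NA_PER_MS_MV
}

#' Optogenetic channel current
#'
#' Zero while the channel is blocked; otherwise Ohmic current toward the
#' chloride reversal with the fixed conductance.
#'
#' @param chan an [opto_channel()].
#' @param V_post membrane potential, mV.
#' @param area membrane area, cm^2.
#' @param unblocked logical: is the channel currently unblocked?
#' @return current in nA (outward-positive).
#' @export
optogenetic_current <- function(chan, V_post, area = membrane_area(10),
                                unblocked = FALSE) {
  stopifnot(inherits(chan, "opto_channel"))
  if (!unblocked) return(0 * V_post)
  chan$g_opto_Cl * area * (V_post - chan$E_opto) * .NA_PER_MS_MV
}
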
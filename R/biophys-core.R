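#' Logistic steady-state activation of a voltage gate
#'
#' All activation/inactivation gates of the two-compartment model share
#' the Boltzmann form 1 / (1 + exp(-(V - V_half)/slope)); a negative slope
#' yields an inactivation curve.
#'
#' @param V membrane potential (mV); vectorised.
#' @param V_half half-activation voltage (mV).
#' @param slope slope factor (mV), non-zero.
#' @return activation in \[0, 1\].
#' @export
gate_steady_state <- function(V, V_half, slope) {
  check(is_number(V_half), "V_half must be a number")
  check(is_number(slope) && slope != 0, "slope must be a non-zero number")
  1 / (1 + exp(-(V - V_half) / slope))
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' B(V) = 1 / (1 + exp(-0.062 V) \[Mg2+\]_o / 3.57): depolarisation relieves
#' the block, and with no extracellular magnesium the pore is never blocked.
#'
#' @param V membrane potential (mV); vectorised.
#' @param Mg_out extracellular magnesium concentration (mM), >= 0.
#' @return blocking factor in (0, 1\].
#' @export
mg_block <- function(V, Mg_out) {
  check(is_number(Mg_out) && Mg_out >= 0, "Mg_out must be a non-negative number")
  1 / (1 + exp(-0.062 * V) * Mg_out / 3.57)
}

#' Ionic currents of the two-compartment model
#'
#' Evaluates every membrane current at a given state: somatic and dendritic
#' fast Na+ (instantaneous m_inf^2 activation; the somatic current uses
#' (1 - n_S) as its inactivation surrogate, the dendritic one an explicit
#' h_D gate), delayed-rectifier K+, dendritic SK with Hill-type calcium
#' activation Ca^2/(Ca^2 + k_Ca^2), the calcium component of the NMDA
#' current g_NMDA B(V_D) \[O\] (V_D - V_Ca), passive leaks, and the
#' resistive coupling currents g_c/kappa (V_S - V_D) and
#' g_c/(1 - kappa) (V_D - V_S).
#'
#' @param state a \code{biophys_state}.
#' @param params a \code{biophys_params}.
#' @param nmda_open open probability of the NMDA receptor (defaults to the
#'   \code{O} component of the state).
#' @return named list of currents (uA/cm^2): I_Na_S, I_K_S, I_Na_D, I_K_D,
#'   I_SK, I_NMDA, I_leak_S, I_leak_D, I_coupling_S, I_coupling_D.
#' @export
ionic_currents <- function(state, params, nmda_open = state[["O"]]) {
  p <- params; s <- state
  gs <- function(g, V) gate_steady_state(V, p$gates[[g]]$V_half, p$gates[[g]]$slope)
  m_S <- gs("m_S", s[["V_S"]]); m_D <- gs("m_D", s[["V_D"]])
  hill <- s[["Ca_i"]]^2 / (s[["Ca_i"]]^2 + p$k_Ca^2)
  list(
    I_Na_S = p$g_Na_S * m_S^2 * (1 - s[["n_S"]]) * (s[["V_S"]] - p$V_Na),
    I_K_S  = p$g_K_S * s[["n_S"]]^2 * (s[["V_S"]] - p$V_K),
    I_Na_D = p$g_Na_D * m_D^2 * s[["h_D"]] * (s[["V_D"]] - p$V_Na),
    I_K_D  = p$g_K_D * s[["n_D"]]^2 * s[["p_D"]] * (s[["V_D"]] - p$V_K),
    I_SK   = p$g_SK * hill * (s[["V_D"]] - p$V_K),
    I_NMDA = p$g_NMDA * mg_block(s[["V_D"]], p$Mg_out) * nmda_open *
      (s[["V_D"]] - p$V_Ca),
    I_leak_S = p$g_leak * (s[["V_S"]] - p$V_leak),
    I_leak_D = p$g_leak * (s[["V_D"]] - p$V_leak),
    I_coupling_S = p$g_c / p$kappa * (s[["V_S"]] - s[["V_D"]]),
    I_coupling_D = p$g_c / (1 - p$kappa) * (s[["V_D"]] - s[["V_S"]])
  )
}

#' Deterministic right-hand side of the two-compartment model
#'
#' Full drift of the coupled membrane / gating / NMDA-Markov / calcium
#' system.  The applied current I_app enters only the somatic equation and
#' the synaptic current only the dendritic one.  Gating variables relax to
#' their steady states with first-order kinetics (x_inf - x)/tau_x; the
#' NMDA occupancy derivative is delegated to \code{\link{markov_rhs}} and
#' the calcium derivatives to \code{\link{calcium_rhs}}.
#'
#' @param state a \code{biophys_state} (named vector of 14 components).
#' @param params a \code{biophys_params}.
#' @param I_syn background synaptic current to the dendrite (uA/cm^2).
#' @param glu glutamate concentration at the NMDA receptor (uM).
#' @return named numeric vector of time derivatives (per ms), same layout
#'   as the state.
#' @export
biophys_rhs <- function(state, params, I_syn = 0, glu = 0) {
  check(all(is.finite(state)), "non-finite state component")
  p <- params; s <- state
  cur <- ionic_currents(s, p)
  dV_S <- (p$I_app - cur$I_Na_S - cur$I_K_S - cur$I_coupling_S -
             cur$I_leak_S) / p$C_m
  dV_D <- (I_syn - cur$I_Na_D - cur$I_K_D - cur$I_SK - cur$I_NMDA -
             cur$I_coupling_D - cur$I_leak_D) / p$C_m
  gate_d <- function(g, x, V) {
    gt <- p$gates[[g]]
    (gate_steady_state(V, gt$V_half, gt$slope) - x) / gt$tau
  }
  docc <- markov_rhs(s[c("C0", "C1", "C2", "O", "D")], p$nmda, glu)
  dca <- calcium_rhs(s[c("Ca_i", "Ca_ER", "h_IP3R")], p$calcium, cur$I_NMDA)
  c(V_S = dV_S, V_D = dV_D,
    n_S = gate_d("n_S", s[["n_S"]], s[["V_S"]]),
    n_D = gate_d("n_D", s[["n_D"]], s[["V_D"]]),
    h_D = gate_d("h_D", s[["h_D"]], s[["V_D"]]),
    p_D = gate_d("p_D", s[["p_D"]], s[["V_D"]]),
    docc, dca)
}
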
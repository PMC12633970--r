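#' Parameters of the dendritic calcium mobilisation model
#'
#' Flux-balance description of cytosolic and ER calcium in the dendritic
#' compartment: NMDA influx, PMCA and SERCA pumps (Hill-saturating),
#' Li-Rinzel IP3-receptor release, and passive membrane/ER leaks.
#'
#' All flux rates are specified in uM/s (the conventional unit for pump
#' rates); the right-hand side converts to the ms time base of the
#' membrane model internally.  IP3R gating constants (d1, d2, d3, d5, a)
#' are the classical Li-Rinzel values; \code{alpha} lumps the
#' current-to-flux conversion 1/(2 F V_D) for the effective dendritic
#' volume and is a calibration constant of the model.
#'
#' @param f_c,f_ER free-calcium fractions of cytosol and ER (0, 1\].
#' @param gamma cytosol-to-ER volume ratio.
#' @param alpha current-to-flux factor (uM cm^2 / (uA s)); converts the
#'   NMDA calcium current density into a cytosolic flux.
#' @param nu_PMCA,nu_SERCA,nu_IP3R,nu_INleak,nu_ERleak maximal flux rates
#'   (uM/s; the leak rates are per second per uM of gradient).
#' @param K_PMCA,K_SERCA pump half-activations (uM).
#' @param iota Hill coefficient of the pumps (2 by convention).
#' @param d1,d2,d3,d5 IP3R dissociation constants (uM).
#' @param a IP3R h-gate rate constant (per uM per s).
#' @param IP3 cytosolic IP3 concentration (uM), held constant.
#' @param Ca_out extracellular calcium (uM).
#' @return an object of class \code{calcium_params}.
#' @export
calcium_params <- function(f_c = 0.05, f_ER = 0.05, gamma = 5,
                           alpha = 40,
                           nu_PMCA = 120, K_PMCA = 0.3,
                           nu_SERCA = 0.9, K_SERCA = 0.1,
                           nu_IP3R = 6, nu_INleak = 2e-4, nu_ERleak = 0.11,
                           iota = 2,
                           d1 = 0.13, d2 = 1.049, d3 = 0.9434, d5 = 0.08234,
                           a = 0.2, IP3 = 0.3, Ca_out = 1500) {
  validate_calcium_params(structure(
    list(f_c = f_c, f_ER = f_ER, gamma = gamma, alpha = alpha,
         nu_PMCA = nu_PMCA, K_PMCA = K_PMCA, nu_SERCA = nu_SERCA,
         K_SERCA = K_SERCA, nu_IP3R = nu_IP3R, nu_INleak = nu_INleak,
         nu_ERleak = nu_ERleak, iota = iota,
         d1 = d1, d2 = d2, d3 = d3, d5 = d5, a = a,
         IP3 = IP3, Ca_out = Ca_out),
    class = "calcium_params"))
}

validate_calcium_params <- function(p) {
  pos <- c("gamma", "alpha", "K_PMCA", "K_SERCA", "iota",
           "d1", "d2", "d3", "d5", "a", "Ca_out")
  for (nm in pos) check(is_number(p[[nm]]) && p[[nm]] > 0, nm, " must be > 0")
  for (nm in c("nu_PMCA", "nu_SERCA", "nu_IP3R", "nu_INleak", "nu_ERleak"))
    check(is_number(p[[nm]]) && p[[nm]] >= 0, nm, " must be >= 0")
  check(is_number(p$IP3) && p$IP3 >= 0, "IP3 must be >= 0")
  for (nm in c("f_c", "f_ER"))
    check(is_number(p[[nm]]) && p[[nm]] > 0 && p[[nm]] <= 1,
          nm, " must lie in (0, 1]")
  p
}

#' Hill-saturating pump flux (PMCA / SERCA)
#'
#' nu Ca^iota / (Ca^iota + K^iota): zero at zero calcium, half-maximal at
#' \code{K}, saturating at \code{nu}.
#'
#' @param Ca_i cytosolic calcium (uM), >= 0; vectorised.
#' @param nu maximal flux rate (uM/s).
#' @param K half-activation (uM).
#' @param iota Hill coefficient.
#' @return flux (uM/s).
#' @export
pump_flux <- function(Ca_i, nu, K, iota = 2) {
  check(is_number(nu) && nu >= 0, "nu must be >= 0")
  check(is_number(K) && K > 0, "K must be > 0")
  check(all(Ca_i >= 0), "negative calcium concentration")
  nu * Ca_i^iota / (Ca_i^iota + K^iota)
}

#' Li-Rinzel IP3-receptor flux
#'
#' nu_IP3R m_inf^3 n_inf^3 h^3 (Ca_ER - Ca_i) with
#' m_inf = IP3/(IP3 + d1) (IP3 binding) and n_inf = Ca_i/(Ca_i + d5)
#' (fast calcium activation); \code{h} is the slow inactivation gate.
#'
#' @param state named vector or \code{calcium_state} with \code{Ca_i},
#'   \code{Ca_ER}, \code{h_IP3R}.
#' @param p a \code{calcium_params}.
#' @return flux (uM/s), positive when the ER releases calcium.
#' @export
ip3r_flux <- function(state, p) {
  m_inf <- p$IP3 / (p$IP3 + p$d1)
  n_inf <- state[["Ca_i"]] / (state[["Ca_i"]] + p$d5)
  p$nu_IP3R * m_inf^3 * n_inf^3 * state[["h_IP3R"]]^3 *
    (state[["Ca_ER"]] - state[["Ca_i"]])
}

#' IP3R inactivation-gate kinetics
#'
#' dh/dt = (h_inf - h)/tau_h with h_inf = Q2/(Q2 + Ca_i),
#' tau_h = 1/(a (Q2 + Ca_i)) and Q2 = d2 (IP3 + d1)/(IP3 + d3):
#' calcium inactivates the receptor on a slow time scale.
#'
#' @inheritParams ip3r_flux
#' @return dh/dt (per s).
#' @export
h_gate_rhs <- function(state, p) {
  Q2 <- p$d2 * (p$IP3 + p$d1) / (p$IP3 + p$d3)
  h_inf <- Q2 / (Q2 + state[["Ca_i"]])
  tau_h <- 1 / (p$a * (Q2 + state[["Ca_i"]]))
  (h_inf - state[["h_IP3R"]]) / tau_h
}

#' Flux-balance derivatives of the calcium subsystem
#'
#' d\[Ca\]_i/dt = f_c (J_NMDA - J_PMCA + J_IP3R + J_ERleak - J_SERCA - J_INleak),
#' d\[Ca\]_ER/dt = f_ER gamma (J_SERCA - J_IP3R - J_ERleak), plus the
#' IP3R h-gate.  J_NMDA = -alpha I_NMDA: the NMDA calcium current is
#' inward (negative by the membrane sign convention), so influx is a
#' positive cytosolic flux.  J_INleak = nu_INleak (Ca_out - Ca_i) and
#' J_ERleak = nu_ERleak (Ca_ER - Ca_i).
#'
#' In a closed-cell configuration (no membrane fluxes) the combination
#' Ca_i/f_c + Ca_ER/(f_ER gamma) is exactly conserved.
#'
#' @param state named vector with \code{Ca_i}, \code{Ca_ER}, \code{h_IP3R}.
#' @param p a \code{calcium_params}.
#' @param I_NMDA NMDA calcium current density (uA/cm^2, inward negative).
#' @param per_ms if TRUE (default) derivatives are returned on the ms time
#'   base of the membrane model; if FALSE in the native per-second base.
#' @return named vector (dCa_i, dCa_ER, dh_IP3R).
#' @export
calcium_rhs <- function(state, p, I_NMDA = 0, per_ms = TRUE) {
  check(all(is.finite(state)) && is.finite(I_NMDA), "non-finite input")
  Ca_i <- state[["Ca_i"]]; Ca_ER <- state[["Ca_ER"]]
  J_NMDA <- -p$alpha * I_NMDA
  J_PMCA <- pump_flux(Ca_i, p$nu_PMCA, p$K_PMCA, p$iota)
  J_SERCA <- pump_flux(Ca_i, p$nu_SERCA, p$K_SERCA, p$iota)
  J_IP3R <- ip3r_flux(state, p)
  J_INleak <- p$nu_INleak * (p$Ca_out - Ca_i)
  J_ERleak <- p$nu_ERleak * (Ca_ER - Ca_i)
  d <- c(
    Ca_i = p$f_c * (J_NMDA - J_PMCA + J_IP3R + J_ERleak - J_SERCA - J_INleak),
    Ca_ER = p$f_ER * p$gamma * (J_SERCA - J_IP3R - J_ERleak),
    h_IP3R = h_gate_rhs(state, p))
  if (per_ms) d / 1000 else d
}
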
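#' Parameters of the two-compartment ELL pyramidal cell model
#'
#' Builds the full parameter set of the conductance-based two-compartment
#' model: somatic and dendritic membrane equations coupled through a
#' resistor, fast Na+ / delayed-rectifier K+ spiking currents in both
#' compartments, dendritic SK (Ca2+-activated K+) and NMDA (Ca2+ component)
#' currents, Markov NMDA receptor kinetics, Li-Rinzel calcium mobilisation
#' and 1/f^beta background synaptic noise.
#'
#' Units follow the ghostbursting-model convention: voltages in mV, time in
#' ms, conductances in mS/cm^2, currents in uA/cm^2, capacitance in
#' uF/cm^2, calcium concentrations in uM.  Calcium flux rates are accepted
#' in uM/s (the usual unit for pump rates) and converted to the ms time
#' base internally at load.
#'
#' The default values for the spiking backbone (Na/K/leak/coupling and the
#' six gating functions) are the classical two-compartment ghostbursting
#' reference set; the SK/NMDA/calcium additions and \code{I_app} are
#' calibration parameters with documented defaults (see the package
#' vignette) and are the natural targets for fitting.
#'
#' @param ... named overrides of any top-level field or of fields inside
#'   the \code{gates}, \code{calcium}, \code{nmda} or \code{noise} groups
#'   (pass the whole group list to override group members).
#' @return an object of class \code{biophys_params}.
#' @examples
#' p <- biophys_params(I_app = 7)
#' p$g_SK
#' @export
biophys_params <- function(...) {
  p <- list(
    # membrane
    C_m = 1, g_c = 1, kappa = 0.4,
    g_Na_S = 55, g_K_S = 20, g_Na_D = 5, g_K_D = 15,
    g_SK = 0.2, g_NMDA = 0.5, g_leak = 0.18,
    I_app = 8,
    # reversals (mV)
    V_Na = 40, V_K = -88.5, V_Ca = 70, V_leak = -70,
    # SK activation and Mg block
    k_Ca = 0.6, Mg_out = 1.0,
    # gating functions: half-activation (mV), slope (mV), tau (ms; NA =
    # instantaneous m_inf)
    gates = list(
      m_S = list(V_half = -40, slope = 3, tau = NA_real_),
      n_S = list(V_half = -40, slope = 3, tau = 0.39),
      m_D = list(V_half = -40, slope = 5, tau = NA_real_),
      h_D = list(V_half = -52, slope = -5, tau = 1.0),
      n_D = list(V_half = -40, slope = 5, tau = 0.9),
      p_D = list(V_half = -65, slope = -6, tau = 5.0)
    ),
    calcium = calcium_params(),
    nmda = nmda_kinetics(),
    noise = list(beta = 1, sigma_eta = 0.5,
                 lambda_glu = 100, A_glu = 2718.28, tau_d_glu = 1.0)
  )
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    check(length(unknown) == 0, "unknown parameter(s): ",
          paste(unknown, collapse = ", "))
    for (nm in names(ov)) {
      if (is.list(p[[nm]]) && is.list(ov[[nm]])) {
        bad <- setdiff(names(ov[[nm]]), names(p[[nm]]))
        check(length(bad) == 0, "unknown ", nm, " parameter(s): ",
              paste(bad, collapse = ", "))
        p[[nm]] <- modifyList(p[[nm]], ov[[nm]])
      } else p[[nm]] <- ov[[nm]]
    }
  }
  validate_biophys_params(structure(p, class = "biophys_params"))
}

validate_biophys_params <- function(p) {
  conds <- c("g_c", "g_Na_S", "g_K_S", "g_Na_D", "g_K_D",
             "g_SK", "g_NMDA", "g_leak")
  for (g in conds) check(is_number(p[[g]]) && p[[g]] >= 0,
                         g, " must be a non-negative number")
  check(is_number(p$C_m) && p$C_m > 0, "C_m must be > 0")
  check(is_number(p$kappa) && p$kappa > 0 && p$kappa < 1,
        "kappa must lie strictly in (0, 1)")
  check(is_number(p$k_Ca) && p$k_Ca > 0, "k_Ca must be > 0")
  check(is_number(p$Mg_out) && p$Mg_out >= 0, "Mg_out must be >= 0")
  for (g in names(p$gates)) {
    gt <- p$gates[[g]]
    check(is_number(gt$V_half), "gate ", g, ": V_half must be a number")
    check(is_number(gt$slope) && gt$slope != 0,
          "gate ", g, ": slope must be non-zero")
    if (!is.na(gt$tau)) check(gt$tau > 0, "gate ", g, ": tau must be > 0")
  }
  validate_calcium_params(p$calcium)
  validate_nmda_kinetics(p$nmda)
  check(p$noise$sigma_eta >= 0, "noise sigma_eta must be >= 0")
  check(p$noise$lambda_glu > 0 && p$noise$A_glu > 0 && p$noise$tau_d_glu > 0,
        "glutamate parameters must be > 0")
  if (p$noise$lambda_glu / 1000 * p$noise$tau_d_glu > 0.1)
    warning("lambda_glu * tau_d_glu > 0.1: glutamate release events will overlap")
  p
}

#' Initial state of the two-compartment model
#'
#' @param V_S,V_D somatic and dendritic membrane potentials (mV).
#' @param n_S,n_D,h_D,p_D gating variables in \[0, 1\] (defaults: steady
#'   state at the given voltages).
#' @param params a \code{biophys_params} object used for gate steady states.
#' @param Ca_i,Ca_ER,h_IP3R calcium subsystem state (uM, uM, gate).
#' @param nmda a \code{markov_occupancy} (defaults to all receptors unbound).
#' @return an object of class \code{biophys_state}: a named numeric vector
#'   with components V_S, V_D, n_S, n_D, h_D, p_D, C0, C1, C2, O, D,
#'   Ca_i, Ca_ER, h_IP3R.
#' @export
biophys_state <- function(V_S = -70, V_D = -70, params = biophys_params(),
                          n_S = NULL, n_D = NULL, h_D = NULL, p_D = NULL,
                          Ca_i = 0.05, Ca_ER = 10, h_IP3R = 0.8,
                          nmda = markov_occupancy()) {
  gs <- function(g, V) gate_steady_state(V, params$gates[[g]]$V_half,
                                         params$gates[[g]]$slope)
  st <- c(V_S = V_S, V_D = V_D,
          n_S = n_S %||% gs("n_S", V_S),
          n_D = n_D %||% gs("n_D", V_D),
          h_D = h_D %||% gs("h_D", V_D),
          p_D = p_D %||% gs("p_D", V_D),
          nmda,
          Ca_i = Ca_i, Ca_ER = Ca_ER, h_IP3R = h_IP3R)
  validate_biophys_state(structure(st, class = "biophys_state"))
}

validate_biophys_state <- function(st) {
  check(all(is.finite(st)), "non-finite state component")
  gv <- st[c("n_S", "n_D", "h_D", "p_D")]
  check(all(gv >= 0 & gv <= 1), "gating variables must lie in [0, 1]")
  check(st["Ca_i"] >= 0 && st["Ca_ER"] >= 0, "calcium concentrations must be >= 0")
  check(st["h_IP3R"] >= 0 && st["h_IP3R"] <= 1, "h_IP3R must lie in [0, 1]")
  occ <- st[c("C0", "C1", "C2", "O", "D")]
  check(all(occ >= 0 & occ <= 1) && abs(sum(occ) - 1) < 1e-9,
        "NMDA occupancies must lie in [0,1] and sum to 1")
  st
}

#' Write model parameters to a JSON document
#'
#' The document groups fields as \code{membrane}, \code{gates},
#' \code{reversals}, \code{calcium}, \code{nmda}, \code{noise} so that a
#' configuration is self-describing; \code{\link{read_params_json}} rejects
#' unknown keys to catch typos.
#'
#' @param params a \code{biophys_params} object.
#' @param path file to write.
#' @export
write_params_json <- function(params, path) {
  doc <- list(
    model = "biophys",
    membrane = params[c("C_m", "g_c", "kappa", "g_Na_S", "g_K_S", "g_Na_D",
                        "g_K_D", "g_SK", "g_NMDA", "g_leak", "I_app",
                        "k_Ca", "Mg_out")],
    gates = params$gates,
    reversals = params[c("V_Na", "V_K", "V_Ca", "V_leak")],
    calcium = unclass(params$calcium),
    nmda = unclass(params$nmda),
    noise = params$noise
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read model parameters from a JSON document
#'
#' @param path JSON file written by \code{\link{write_params_json}} or
#'   \code{\link{write_hr_params_json}} (dispatches on the \code{model} key).
#' @return a \code{biophys_params} or \code{hr_params} object.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check(!is.null(doc$model), "parameter document lacks a 'model' key")
  if (doc$model %in% c("hr_modified", "hr_classic"))
    return(do.call(hr_params, c(doc$params, list(model = doc$model))))
  check(identical(doc$model, "biophys"), "unknown model: ", doc$model)
  groups <- c("membrane", "gates", "reversals", "calcium", "nmda", "noise")
  unknown <- setdiff(names(doc), c("model", groups))
  check(length(unknown) == 0, "unknown key(s) in parameter document: ",
        paste(unknown, collapse = ", "))
  gates <- lapply(doc$gates, function(g) {
    g$tau <- g$tau %||% NA_real_
    g[c("V_half", "slope", "tau")]
  })
  do.call(biophys_params, c(
    doc$membrane, doc$reversals,
    list(gates = gates,
         calcium = as.list(doc$calcium),
         nmda = as.list(doc$nmda),
         noise = as.list(doc$noise))))
}
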
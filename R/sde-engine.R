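#' Simulation configuration
#'
#' Fixed-step Euler-Maruyama configuration shared by both models.  The
#' recording rate must divide the stepping rate exactly; recorded samples
#' are taken by pure decimation (every k-th integration step, no
#' interpolation or filtering), which preserves spike peaks at these
#' rates.  Conventions follow the study design: the biophysical model is
#' stepped at 100 kHz and recorded at 10 kHz, the Hindmarsh-Rose model
#' stepped at 20 kHz and recorded at 10 kHz.
#'
#' @param dt integration step (s), > 0.
#' @param duration total simulated time (s), > burn_in.
#' @param seed master seed for all noise streams.
#' @param record_rate output sampling rate (Hz); must divide 1/dt.
#' @param burn_in initial transient discarded from the output (s).
#' @param record_vars names of state variables to record (NULL = all).
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(dt = 1e-4, duration = 5, seed = 1,
                       record_rate = 10000, burn_in = 0,
                       record_vars = NULL) {
  check(is_number(dt) && dt > 0, "dt must be > 0")
  check(is_number(duration) && is_number(burn_in) &&
          duration > burn_in && burn_in >= 0,
        "must have duration > burn_in >= 0")
  check(is_number(record_rate) && record_rate > 0 &&
          record_rate <= 1 / dt + 1e-9, "record_rate must be <= 1/dt")
  k <- (1 / dt) / record_rate
  check(abs(k - round(k)) < 1e-6, "record_rate must divide 1/dt exactly")
  structure(list(dt = dt, duration = duration, seed = seed,
                 record_rate = record_rate, burn_in = burn_in,
                 record_vars = record_vars, decimation = as.integer(round(k))),
            class = "sim_config")
}

new_trajectory <- function(t, values, config, params = NULL) {
  structure(list(t = t, values = values, config = config, params = params),
            class = "trajectory")
}

#' Extract one recorded variable as a (t, v) data frame
#'
#' @param tr a \code{trajectory}.
#' @param var variable name (default: first recorded variable).
#' @return data frame with columns \code{t_s} and \code{v}, the layout
#'   used by the analysis functions for voltage traces.
#' @export
trace_df <- function(tr, var = names(tr$values)[1]) {
  check(var %in% names(tr$values), "variable not recorded: ", var)
  data.frame(t_s = tr$t, v = tr$values[[var]])
}

#' Fixed-step Euler-Maruyama integration of a generic SDE
#'
#' X_{k+1} = X_k + f(X_k) dt + sigma sqrt(dt) xi_k with xi_k independent
#' standard normal deviates, drawn independently for every noisy state
#' variable at every step from one seeded stream.  With all noise
#' intensities zero the scheme reduces exactly to forward Euler.  The
#' output is decimated to \code{config$record_rate}.
#'
#' This generic driver takes an arbitrary R drift function and is meant
#' for small systems and validation studies (e.g. Ornstein-Uhlenbeck
#' benchmarks); the two neuron models use dedicated compiled steppers
#' (\code{\link{simulate_hr}}, \code{\link{simulate_biophys}}) with the
#' same scheme.
#'
#' @param rhs function(state) returning the drift (named vector, per s).
#' @param noise_map named vector of noise intensities sigma per state
#'   variable (missing names = 0).
#' @param state0 named numeric initial state.
#' @param config a \code{sim_config}.
#' @return a \code{trajectory}.
#' @export
integrate_sde <- function(rhs, noise_map, state0, config) {
  check(inherits(config, "sim_config"), "config must be a sim_config")
  check(all(is.finite(state0)), "state0 must be finite")
  nms <- names(state0)
  sig <- setNames(numeric(length(state0)), nms)
  if (length(noise_map)) {
    check(all(names(noise_map) %in% nms), "noise_map names must match state")
    sig[names(noise_map)] <- noise_map
  }
  noisy <- sig > 0
  n_steps <- round(config$duration / config$dt)
  dec <- config$decimation
  keep <- which(nms %in% (config$record_vars %||% nms))
  n_rec <- n_steps %/% dec
  out <- matrix(NA_real_, n_rec, length(keep))
  x <- unname(state0)
  sq <- sqrt(config$dt)
  withr_seed(config$seed, {
    for (k in seq_len(n_steps)) {
      dx <- unname(rhs(setNames(x, nms))) * config$dt
      if (any(noisy)) dx[noisy] <- dx[noisy] + sig[noisy] * sq * rnorm(sum(noisy))
      x <- x + dx
      if (!all(is.finite(x)))
        stop("non-finite state at step ", k, " (t = ", k * config$dt, " s)")
      if (k %% dec == 0) out[k %/% dec, ] <- x[keep]
    }
  })
  t <- seq_len(n_rec) / config$record_rate
  sel <- t > config$burn_in
  new_trajectory(t[sel] - config$burn_in,
                 setNames(as.data.frame(out[sel, , drop = FALSE]), nms[keep]),
                 config)
}

#' Simulate the (modified) Hindmarsh-Rose model
#'
#' Euler-Maruyama integration of the four-variable stochastic system via
#' a compiled stepper, at a 20 kHz step with 10 kHz recording by default.
#' Noise deviates are drawn from R's seeded generator, so runs are
#' reproducible per seed; with all intensities zero the trajectory is
#' deterministic and bit-reproducible.
#'
#' @param p an \code{hr_params}.
#' @param duration simulated time (s).
#' @param dt integration step (s); default 5e-5 (20 kHz).
#' @param record_rate output rate (Hz); default 10000.
#' @param burn_in discarded transient (s).
#' @param seed integer seed.
#' @param state0 an \code{hr_state}.
#' @return a \code{trajectory} with variables V, y, z, u.
#' @export
simulate_hr <- function(p, duration = 5, dt = 5e-5, record_rate = 10000,
                        burn_in = 0, seed = 1, state0 = hr_state()) {
  check(inherits(p, "hr_params"), "p must be an hr_params")
  cfg <- sim_config(dt = dt, duration = duration, seed = seed,
                    record_rate = record_rate, burn_in = burn_in)
  n_steps <- round(duration / dt)
  pv <- unlist(p[c("a", "b", "c", "d", "r", "s", "V_R", "gamma_u",
                   "alpha_z", "gamma_d", "x_V", "x_z", "k_n", "k_h",
                   "I_app", "sigma_V", "sigma_y", "sigma_z", "sigma_u",
                   "t_scale")])
  out <- withr_seed(seed,
    hr_integrate_cpp(pv, unclass(state0), dt, as.integer(n_steps),
                     cfg$decimation))
  colnames(out) <- c("V", "y", "z", "u")
  t <- seq_len(nrow(out)) / record_rate
  sel <- t > burn_in
  new_trajectory(t[sel] - burn_in, as.data.frame(out[sel, , drop = FALSE]),
                 cfg, params = p)
}

#' Simulate the two-compartment biophysical model
#'
#' Integrates the full 14-variable system (membrane voltages, gates,
#' NMDA Markov occupancies, calcium subsystem) with forward
#' Euler-Maruyama at a 0.1 ms step, recording at 10 kHz by default.
#' The stochastic drive has two components, both reproducible from the
#' master seed: the 1/f^beta background synaptic current entering the
#' dendritic voltage equation, and Poisson glutamate release driving the
#' NMDA receptor.  Setting \code{noise$sigma_eta = 0} and
#' \code{stochastic_glu = FALSE} gives a fully deterministic run.
#'
#' @param p a \code{biophys_params}.
#' @param duration simulated time (s).
#' @param dt integration step (s); default 1e-5 (100 kHz stepping,
#'   required to resolve the fast Na upstroke).
#' @param record_rate output rate (Hz).
#' @param burn_in discarded transient (s).
#' @param seed master seed (noise and glutamate streams are derived from
#'   it).
#' @param state0 a \code{biophys_state}.
#' @param stochastic_glu if FALSE no glutamate is released (NMDA stays
#'   shut); if a \code{glutamate_train}, that train is used (frozen
#'   drive).
#' @param record_vars subset of state names to record (default V_S, V_D,
#'   Ca_i, Ca_ER, h_IP3R, O).
#' @return a \code{trajectory}.
#' @export
simulate_biophys <- function(p, duration = 5, dt = 1e-5, record_rate = 10000,
                             burn_in = 0, seed = 1,
                             state0 = biophys_state(params = p),
                             stochastic_glu = TRUE,
                             record_vars = c("V_S", "V_D", "Ca_i", "Ca_ER",
                                             "h_IP3R", "O")) {
  check(inherits(p, "biophys_params"), "p must be a biophys_params")
  cfg <- sim_config(dt = dt, duration = duration, seed = seed,
                    record_rate = record_rate, burn_in = burn_in,
                    record_vars = record_vars)
  n_steps <- round(duration / dt)
  dt_ms <- dt * 1000
  # background synaptic current (precomputed series at the stepping rate)
  if (p$noise$sigma_eta > 0) {
    I_syn <- synthesize_noise(noise_spec(
      beta = p$noise$beta, sigma_eta = p$noise$sigma_eta,
      duration = duration, sample_rate = 1 / dt,
      seed = derive_seed(seed, 1L)))
  } else I_syn <- numeric(n_steps)
  # glutamate drive
  if (isFALSE(stochastic_glu)) {
    glu <- numeric(n_steps)
  } else {
    train <- if (inherits(stochastic_glu, "glutamate_train")) stochastic_glu
      else sample_release_times(p$noise$lambda_glu, duration,
                                seed = derive_seed(seed, 2L),
                                A_glu = p$noise$A_glu,
                                tau_d = p$noise$tau_d_glu)
    glu <- glutamate_series(train, dt_ms, n_steps)
  }
  pv <- biophys_param_vector(p)
  out <- biophys_integrate_cpp(pv, unclass(state0), dt_ms,
                               as.integer(n_steps), cfg$decimation,
                               I_syn, glu)
  state_names <- c("V_S", "V_D", "n_S", "n_D", "h_D", "p_D",
                   "C0", "C1", "C2", "O", "D", "Ca_i", "Ca_ER", "h_IP3R")
  colnames(out) <- state_names
  keep <- intersect(record_vars %||% state_names, state_names)
  t <- seq_len(nrow(out)) / record_rate
  sel <- t > burn_in
  new_trajectory(t[sel] - burn_in,
                 as.data.frame(out[sel, keep, drop = FALSE]),
                 cfg, params = p)
}

# fixed-order flattening consumed by the compiled stepper
biophys_param_vector <- function(p) {
  g <- p$gates; ca <- p$calcium; k <- p$nmda
  c(p$C_m, p$g_c, p$kappa, p$g_Na_S, p$g_K_S, p$g_Na_D, p$g_K_D,
    p$g_SK, p$g_NMDA, p$g_leak, p$I_app,
    p$V_Na, p$V_K, p$V_Ca, p$V_leak, p$k_Ca, p$Mg_out,
    g$m_S$V_half, g$m_S$slope,
    g$n_S$V_half, g$n_S$slope, g$n_S$tau,
    g$m_D$V_half, g$m_D$slope,
    g$h_D$V_half, g$h_D$slope, g$h_D$tau,
    g$n_D$V_half, g$n_D$slope, g$n_D$tau,
    g$p_D$V_half, g$p_D$slope, g$p_D$tau,
    ca$f_c, ca$f_ER, ca$gamma, ca$alpha,
    ca$nu_PMCA, ca$K_PMCA, ca$nu_SERCA, ca$K_SERCA,
    ca$nu_IP3R, ca$nu_INleak, ca$nu_ERleak, ca$iota,
    ca$d1, ca$d2, ca$d3, ca$d5, ca$a, ca$IP3, ca$Ca_out,
    k$l_b, k$l_u, k$l_o, k$l_c, k$l_d, k$l_r)
}

#' Export a trajectory to CSV
#'
#' Column \code{t_s} followed by each recorded variable, full double
#' precision.
#' @param tr a \code{trajectory}.
#' @param path file to write.
#' @export
write_trajectory_csv <- function(tr, path) {
  df <- cbind(data.frame(t_s = tr$t), tr$values)
  write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
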
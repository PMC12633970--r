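#' Parameters of the (modified) Hindmarsh-Rose model
#'
#' The classic three-variable Hindmarsh-Rose model (fast voltage-like V,
#' fast recovery y, slow adaptation z) is extended with a second slow
#' adaptation variable u whose drift
#' du = -gamma_u n_inf(V) + alpha_z h_inf(z) - gamma_d u couples a
#' voltage-dependent activation gate and a z-dependent inactivation gate
#' (both tanh sigmoids).  All variables are dimensionless; time is in
#' seconds, with the dimensionless HR time unit mapped to physical time
#' through \code{t_scale} (default 1000 per second, i.e. one HR time unit
#' = 1 ms) so that firing rates land in the 5-60 Hz range of in vivo
#' recordings.  Noise enters each equation as an independent additive
#' Wiener increment with intensity \code{sigma_V}, \code{sigma_y},
#' \code{sigma_z}, \code{sigma_u}, expressed per square-root HR time
#' unit so that drift and diffusion rescale together under
#' \code{t_scale}.
#'
#' Classic coefficients (a, b, c, d, r, s, V_R) take their literature
#' values; the new coefficients default to a calibrated set under which
#' an increasing-current sweep passes through quiescence, tonic firing
#' and bursting in that order (see the package vignette).
#'
#' @param a,b,c,d fast-subsystem cubic/quadratic coefficients.
#' @param r slow rate of z.
#' @param s slow gain of z.
#' @param V_R reference (resting) potential of the z equation.
#' @param gamma_u u-activation coefficient (drive from the V gate).
#' @param alpha_z z-coupling coefficient (drive from the z gate).
#' @param gamma_d decay (inhibitory) coefficient of u.
#' @param x_V,x_z gate midpoints for the V and z gates.
#' @param k_n,k_h gate slopes (non-zero).
#' @param I_app applied current (dimensionless).
#' @param sigma_V,sigma_y,sigma_z,sigma_u noise intensities (>= 0).
#' @param t_scale HR time units per second.
#' @param model "hr_modified" or "hr_classic" (classic forces
#'   gamma_u = alpha_z = sigma_u = 0).
#' @return an object of class \code{hr_params}.
#' @export
hr_params <- function(a = 1, b = 3, c = 1, d = 5, r = 0.006, s = 4,
                      V_R = -1.6,
                      gamma_u = 0.1, alpha_z = 0.3, gamma_d = 0.1,
                      x_V = -0.4, x_z = 2.8, k_n = 0.4, k_h = 0.4,
                      I_app = 2.6,
                      sigma_V = 0, sigma_y = 0, sigma_z = 0, sigma_u = 0,
                      t_scale = 1000, model = "hr_modified") {
  check(model %in% c("hr_modified", "hr_classic"),
        "model must be 'hr_modified' or 'hr_classic'")
  if (model == "hr_classic") { gamma_u <- 0; alpha_z <- 0; sigma_u <- 0 }
  p <- structure(
    list(a = a, b = b, c = c, d = d, r = r, s = s, V_R = V_R,
         gamma_u = gamma_u, alpha_z = alpha_z, gamma_d = gamma_d,
         x_V = x_V, x_z = x_z, k_n = k_n, k_h = k_h, I_app = I_app,
         sigma_V = sigma_V, sigma_y = sigma_y, sigma_z = sigma_z,
         sigma_u = sigma_u, t_scale = t_scale, model = model),
    class = "hr_params")
  validate_hr_params(p)
}

validate_hr_params <- function(p) {
  check(p$k_n != 0 && p$k_h != 0, "gate slopes k_n, k_h must be non-zero")
  check(p$gamma_d >= 0, "gamma_d must be >= 0")
  for (nm in c("sigma_V", "sigma_y", "sigma_z", "sigma_u"))
    check(is_number(p[[nm]]) && p[[nm]] >= 0, nm, " must be >= 0")
  check(is_number(p$t_scale) && p$t_scale > 0, "t_scale must be > 0")
  p
}

#' Steady-state gates of the modified Hindmarsh-Rose model
#'
#' n_inf(V) = (1 + tanh((V - x_V)/k_n))/2 and
#' h_inf(z) = (1 + tanh((z - x_z)/k_h))/2.
#'
#' @param V,z state components (vectorised).
#' @param p an \code{hr_params}.
#' @return list with components \code{n_inf} and \code{h_inf} in \[0, 1\].
#' @export
hr_gates <- function(V, z, p) {
  list(n_inf = 0.5 * (1 + tanh((V - p$x_V) / p$k_n)),
       h_inf = 0.5 * (1 + tanh((z - p$x_z) / p$k_h)))
}

#' Deterministic drift of the (modified) Hindmarsh-Rose model
#'
#' dV = y - aV^3 + bV^2 - z - u + I_app; dy = c - dV^2 - y;
#' dz = r(s(V - V_R) - z); du = -gamma_u n_inf(V) + alpha_z h_inf(z)
#' - gamma_d u.  With gamma_u = alpha_z = 0 and u = 0 the system reduces
#' exactly to the classic three-variable model.  Derivatives are per HR
#' time unit; multiply by \code{p$t_scale} for per-second rates.
#'
#' @param state named vector (V, y, z, u) or \code{hr_state}.
#' @param p an \code{hr_params}.
#' @return named vector of drifts (per HR time unit).
#' @export
hr_drift <- function(state, p) {
  check(all(is.finite(state)), "non-finite state component")
  V <- state[["V"]]; y <- state[["y"]]; z <- state[["z"]]; u <- state[["u"]]
  g <- hr_gates(V, z, p)
  c(V = y - p$a * V * V * V + p$b * V * V - z - u + p$I_app,
    y = p$c - p$d * V * V - y,
    z = p$r * (p$s * (V - p$V_R) - z),
    u = -p$gamma_u * g$n_inf + p$alpha_z * g$h_inf - p$gamma_d * u)
}

#' Initial state of the Hindmarsh-Rose model
#' @param V,y,z,u dimensionless state components.
#' @return named numeric vector of class \code{hr_state}.
#' @export
hr_state <- function(V = -1.6, y = -12, z = 0, u = 0) {
  st <- c(V = V, y = y, z = z, u = u)
  check(all(is.finite(st)), "state must be finite")
  structure(st, class = "hr_state")
}

#' Locate the resting equilibrium of the deterministic model
#'
#' Damped-Newton iteration on the four-dimensional drift from a
#' hyperpolarised start.  Returns NULL when no equilibrium is found.
#'
#' @param p an \code{hr_params}.
#' @param start initial guess (defaults to a hyperpolarised state).
#' @return an \code{hr_state} with \eqn{\|drift\| < 1e-10}, or NULL.
#' @export
hr_equilibrium <- function(p, start = hr_state(V = -1.6, y = -11.8, z = 0, u = 0)) {
  x <- unname(unclass(start))
  f <- function(v) {
    v <- unname(v)
    unname(hr_drift(c(V = v[1], y = v[2], z = v[3], u = v[4]), p))
  }
  for (iter in 1:200) {
    fx <- f(x)
    if (sqrt(sum(fx^2)) < 1e-12) break
    J <- vapply(1:4, function(j) {
      h <- max(1e-7, 1e-7 * abs(x[j])); xp <- x; xp[j] <- x[j] + h
      (f(xp) - fx) / h
    }, numeric(4))
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (sqrt(sum(f(xn)^2)) < sqrt(sum(fx^2)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  if (sqrt(sum(f(x)^2)) < 1e-10)
    hr_state(V = x[1], y = x[2], z = x[3], u = x[4]) else NULL
}

#' Classify subthreshold excitability of the modified HR model
#'
#' For a subthreshold applied current, perturbed initial conditions either
#' decay straight back to rest or fire exactly one transient spike before
#' settling (type-IV-like excitability).  Each initial state is simulated
#' deterministically and labelled by the number of spikes emitted before
#' the trajectory re-enters a neighbourhood of the resting equilibrium.
#'
#' @param p an \code{hr_params} (noise intensities are ignored).
#' @param I_app_sub subthreshold applied current (overrides \code{p$I_app}).
#' @param perturbations list of initial \code{hr_state}s.
#' @param duration simulated time (s).
#' @param tol distance from equilibrium regarded as "at rest".
#' @return character vector per initial state: "rest", "single_spike" or
#'   "multi_spike".
#' @export
classify_excitability <- function(p, I_app_sub, perturbations,
                                  duration = 1, tol = 0.05) {
  p <- validate_hr_params(modifyList(p, list(I_app = I_app_sub,
                                             sigma_V = 0, sigma_y = 0,
                                             sigma_z = 0, sigma_u = 0)))
  eq <- hr_equilibrium(p)
  if (is.null(eq))
    stop_invalid("no stable resting equilibrium at I_app = ", I_app_sub)
  vapply(perturbations, function(st) {
    tr <- simulate_hr(p, state0 = st, duration = duration, seed = 1,
                      record_rate = 10000)
    spikes <- detect_spikes(trace_df(tr, "V"), threshold = 0,
                            baseline_relative = FALSE)
    endpt <- vapply(c("V", "y", "z", "u"),
                    function(v) tail(tr$values[[v]], 1), numeric(1))
    at_rest <- sqrt(sum((endpt - unclass(eq))^2)) < max(tol, 1e-3) * 10
    n <- length(spikes$spike_times)
    if (n == 0) "rest" else if (n == 1 && at_rest) "single_spike" else "multi_spike"
  }, character(1))
}
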
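#' Markov NMDA receptor kinetics
#'
#' Transition rates of the five-state ligand-gated scheme
#' C0 = C1 = C2 = O with a desensitised state D branching from C2.
#' Both binding steps (C0 -> C1 -> C2) proceed at \code{l_b} per uM of
#' glutamate, unbinding at \code{l_u}, channel opening C2 -> O at
#' \code{l_o}, closing O -> C2 at \code{l_c}, desensitisation C2 -> D at
#' \code{l_d} and recovery D -> C2 at \code{l_r}.  Default rates follow
#' the classical kinetic fits of whole-cell NMDA currents
#' (5e6 /M/s binding; unbinding 12.9 /s; opening 46.5 /s; closing 73.8 /s;
#' desensitisation 8.4 /s; recovery 6.8 /s), converted to per-ms.
#'
#' @param l_b binding rate (per uM per ms).
#' @param l_u unbinding rate (per ms).
#' @param l_o,l_c opening / closing rates (per ms).
#' @param l_d,l_r desensitisation / recovery rates (per ms).
#' @return an object of class \code{nmda_kinetics}.
#' @export
nmda_kinetics <- function(l_b = 5e-3, l_u = 12.9e-3, l_o = 46.5e-3,
                          l_c = 73.8e-3, l_d = 8.4e-3, l_r = 6.8e-3) {
  validate_nmda_kinetics(structure(
    list(l_b = l_b, l_u = l_u, l_o = l_o, l_c = l_c, l_d = l_d, l_r = l_r),
    class = "nmda_kinetics"))
}

validate_nmda_kinetics <- function(k) {
  for (nm in c("l_b", "l_u", "l_o", "l_c", "l_d", "l_r"))
    check(is_number(k[[nm]]) && k[[nm]] >= 0, nm, " must be a non-negative rate")
  k
}

#' NMDA receptor state occupancy
#'
#' @param C0,C1,C2,O,D state probabilities; must be in \[0,1\] and sum to 1.
#' @return named numeric vector of class \code{markov_occupancy}.
#' @export
markov_occupancy <- function(C0 = 1, C1 = 0, C2 = 0, O = 0, D = 0) {
  occ <- c(C0 = C0, C1 = C1, C2 = C2, O = O, D = D)
  check(all(occ >= 0 & occ <= 1), "occupancies must lie in [0, 1]")
  check(abs(sum(occ) - 1) < 1e-9, "occupancies must sum to 1")
  structure(occ, class = "markov_occupancy")
}

#' Transition-rate matrix of the NMDA Markov scheme
#'
#' @param kin an \code{nmda_kinetics}.
#' @param glu glutamate concentration (uM).
#' @return 5x5 generator matrix Q with d occ/dt = Q occ (columns sum to 0).
#' @export
nmda_rate_matrix <- function(kin, glu) {
  k <- kin; b <- k$l_b * glu
  # columns: source state; rows: destination
  Q <- matrix(0, 5, 5, dimnames = list(c("C0","C1","C2","O","D"),
                                       c("C0","C1","C2","O","D")))
  Q["C1","C0"] <- b;      Q["C0","C1"] <- k$l_u
  Q["C2","C1"] <- b;      Q["C1","C2"] <- k$l_u
  Q["O","C2"]  <- k$l_o;  Q["C2","O"]  <- k$l_c
  Q["D","C2"]  <- k$l_d;  Q["C2","D"]  <- k$l_r
  diag(Q) <- -colSums(Q)
  Q
}

#' Master-equation derivative of the NMDA occupancy
#'
#' Deterministic (ensemble) occupancy dynamics: a linear master equation
#' whose derivatives sum to zero exactly, so total probability is
#' conserved.
#'
#' @param occ a \code{markov_occupancy} (or named vector C0..D).
#' @param kin an \code{nmda_kinetics}.
#' @param glu glutamate concentration (uM).
#' @return named vector of occupancy derivatives (per ms).
#' @export
markov_rhs <- function(occ, kin, glu) {
  b <- kin$l_b * glu
  dC0 <- kin$l_u * occ[["C1"]] - b * occ[["C0"]]
  dC1 <- b * occ[["C0"]] + kin$l_u * occ[["C2"]] -
    (kin$l_u + b) * occ[["C1"]]
  dC2 <- b * occ[["C1"]] + kin$l_c * occ[["O"]] + kin$l_r * occ[["D"]] -
    (kin$l_u + kin$l_o + kin$l_d) * occ[["C2"]]
  dO <- kin$l_o * occ[["C2"]] - kin$l_c * occ[["O"]]
  dD <- kin$l_d * occ[["C2"]] - kin$l_r * occ[["D"]]
  c(C0 = dC0, C1 = dC1, C2 = dC2, O = dO, D = dD)
}

#' Poisson glutamate release train
#'
#' Release times follow a homogeneous Poisson process with rate
#' \code{rate}; each release produces an alpha-function glutamate
#' transient (see \code{\link{glutamate_concentration}}).
#'
#' @param rate release rate (events/s), > 0.
#' @param duration train duration (s), > 0.
#' @param seed integer seed; the train is reproducible per seed.
#' @param A_glu amplitude scale (uM/ms).
#' @param tau_d decay time constant of the alpha function (ms).
#' @return an object of class \code{glutamate_train} with fields
#'   \code{release_times} (s, sorted), \code{rate}, \code{duration},
#'   \code{A_glu}, \code{tau_d}.
#' @export
sample_release_times <- function(rate, duration, seed,
                                 A_glu = 2718.28, tau_d = 1.0) {
  check(is_number(rate) && rate > 0, "rate must be > 0")
  check(is_number(duration) && duration > 0, "duration must be > 0")
  check(A_glu > 0 && tau_d > 0, "A_glu and tau_d must be > 0")
  withr_seed(seed, {
    n <- stats::rpois(1, rate * duration)
    times <- sort(runif(n, 0, duration))
  })
  structure(list(release_times = times, rate = rate, duration = duration,
                 A_glu = A_glu, tau_d = tau_d),
            class = "glutamate_train")
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Glutamate concentration from a release train
#'
#' Each release at tau_r contributes an alpha-function transient
#' A_glu (t - tau_r) exp(-(t - tau_r)/tau_d) H(t - tau_r) with the elapsed
#' time measured in ms; transients superpose linearly.  A single event
#' peaks at tau_r + tau_d with amplitude A_glu tau_d / e.
#'
#' @param t time (s); vectorised.
#' @param train a \code{glutamate_train}.
#' @return glutamate concentration (uM), >= 0.
#' @export
glutamate_concentration <- function(t, train) {
  check(all(is.finite(t)), "t must be finite")
  vapply(t, function(tt) {
    dt_ms <- (tt - train$release_times) * 1000
    dt_ms <- dt_ms[dt_ms > 0 & dt_ms < 40 * train$tau_d]
    if (!length(dt_ms)) return(0)
    sum(train$A_glu * dt_ms * exp(-dt_ms / train$tau_d))
  }, numeric(1))
}

# glutamate series on a uniform ms grid by discrete convolution of the
# event impulse train with the alpha kernel (exact for grid-aligned events)
glutamate_series <- function(train, dt_ms, n_steps) {
  impulses <- numeric(n_steps)
  idx <- floor(train$release_times * 1000 / dt_ms) + 1
  idx <- idx[idx >= 1 & idx <= n_steps]
  for (i in idx) impulses[i] <- impulses[i] + 1
  klen <- min(n_steps, ceiling(40 * train$tau_d / dt_ms))
  tk <- (seq_len(klen) - 1) * dt_ms
  kernel <- train$A_glu * tk * exp(-tk / train$tau_d)
  if (!any(impulses > 0)) return(numeric(n_steps))
  # FFT convolution, truncated back to the grid
  nfft <- stats::nextn(n_steps + klen - 1, 2)
  gi <- Re(fft(fft(c(impulses, numeric(nfft - n_steps))) *
               fft(c(kernel, numeric(nfft - klen))), inverse = TRUE)) / nfft
  pmax(gi[seq_len(n_steps)], 0)
}

#' Export a glutamate train to CSV
#'
#' One release time (seconds) per row, column \code{release_time_s}.
#' @param train a \code{glutamate_train}.
#' @param path file to write.
#' @export
write_glutamate_csv <- function(train, path) {
  write.csv(data.frame(release_time_s = train$release_times), path,
            row.names = FALSE)
  invisible(path)
}
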
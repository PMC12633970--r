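# Independent oracles and synthetic fixture builders shared across tests.

# brute-force burst enumeration: scan all maximal runs of consecutive
# sub-threshold ISIs, independent of the package's rle-based partition
oracle_burst_fraction <- function(times, thr) {
  n <- length(times)
  if (n < 2) return(list(burst_fraction = 0, sizes = integer(0)))
  in_burst <- rep(FALSE, n)
  sizes <- integer(0)
  i <- 1
  while (i < n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) < thr) j <- j + 1
    if (j > i) {
      in_burst[i:j] <- TRUE
      sizes <- c(sizes, j - i + 1L)
      i <- j + 1
    } else i <- i + 1
  }
  list(burst_fraction = sum(in_burst) / n, sizes = sizes)
}

# exhaustive two-sample KS statistic: sup of |ECDF difference| over every
# pooled breakpoint
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  Fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(Fx - Fy))
}

# stationary occupancy of the NMDA scheme at constant glutamate from the
# null space of the generator matrix (linear-algebra route)
oracle_markov_stationary <- function(kin, glu) {
  Q <- nmda_rate_matrix(kin, glu)
  ns <- svd(Q)$v[, 5]
  ns / sum(ns)
}

# simple R-side Euler integrator for a named-state ODE (no noise)
euler_integrate <- function(rhs, state, dt, n_steps, ...) {
  out <- matrix(NA_real_, n_steps, length(state),
                dimnames = list(NULL, names(state)))
  for (k in seq_len(n_steps)) {
    state <- state + rhs(state, ...) * dt
    out[k, ] <- state
  }
  out
}

# synthetic voltage trace: Gaussian bumps of given peak over a baseline
bump_trace <- function(bump_times, duration = 1, fs = 10000,
                       baseline = -70, peak = -10, width = 0.0004) {
  t <- seq(0, duration, by = 1 / fs)
  v <- rep(baseline, length(t))
  for (bt in bump_times)
    v <- v + (peak - baseline) * exp(-(t - bt)^2 / (2 * width^2))
  data.frame(t_s = t, v = v)
}

# wrap a voltage vector as a minimal trajectory object
as_traj <- function(v, fs = 10000) {
  structure(list(t = seq_along(v) / fs,
                 values = data.frame(V = v),
                 config = NULL, params = NULL),
            class = "trajectory")
}

# random spike train with a mix of short and long ISIs
random_spike_train <- function(n_isi, p_short = 0.5) {
  isis <- ifelse(runif(n_isi) < p_short,
                 runif(n_isi, 0.002, 0.011),
                 runif(n_isi, 0.013, 0.25))
  times <- cumsum(isis)
  spike_train(times, duration = sum(isis) + 0.1)
}

# damped Newton with finite-difference Jacobian; generic root oracle for
# stiff steady-state checks (seeded from an integrated state)
newton_root <- function(f, x0, tol = 1e-12, maxit = 100) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    nf <- sqrt(sum(fx^2))
    if (nf < tol) break
    J <- vapply(seq_along(x), function(j) {
      h <- max(1e-8, 1e-8 * abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      (f(xp) - fx) / h
    }, numeric(length(x)))
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x + lam * step
      ok <- tryCatch(sqrt(sum(f(xn)^2)) < nf, error = function(e) FALSE)
      if (ok || lam < 1e-8) break
      lam <- lam / 2
    }
    if (lam < 1e-8) break
    x <- xn
  }
  x
}
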
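test_that("pump flux follows the Hill form at its anchor points", {
  expect_equal(pump_flux(0, 10, 0.3), 0)
  expect_equal(pump_flux(0.3, 10, 0.3), 5)
  expect_equal(pump_flux(0.9, 10, 0.3, iota = 2), 10 * 9 / 10)
  x <- seq(0, 5, by = 0.01)
  fx <- pump_flux(x, 10, 0.3)
  expect_true(all(diff(fx) > 0))
  expect_true(all(fx <= 10))
  expect_error(pump_flux(-0.1, 10, 0.3), "negative")
})

test_that("IP3R flux respects its half-activation anchors and gradient sign", {
  p <- calcium_params()
  st <- c(Ca_i = 0.2, Ca_ER = 0.2, h_IP3R = 0.5)
  expect_equal(ip3r_flux(st, p), 0)
  p2 <- calcium_params(IP3 = p$d1)
  st2 <- c(Ca_i = p2$d5, Ca_ER = 12, h_IP3R = 1)
  expect_equal(ip3r_flux(st2, p2),
               p2$nu_IP3R * 0.5^3 * 0.5^3 * (12 - p2$d5))
  st3 <- c(Ca_i = 0.1, Ca_ER = 12, h_IP3R = 0)
  expect_equal(ip3r_flux(st3, p), 0)
  # release reverses with the gradient
  st4 <- c(Ca_i = 5, Ca_ER = 1, h_IP3R = 0.8)
  expect_lt(ip3r_flux(st4, p), 0)
})

test_that("the h gate fixes at Q2 and its steady state falls with calcium", {
  p <- calcium_params()
  Q2 <- p$d2 * (p$IP3 + p$d1) / (p$IP3 + p$d3)
  expect_equal(h_gate_rhs(c(Ca_i = Q2, Ca_ER = 5, h_IP3R = 0.5), p), 0)
  ca <- seq(0, 3, by = 0.01)
  h_inf <- Q2 / (Q2 + ca)
  expect_true(all(diff(h_inf) < 0))
  tau <- 1 / (p$a * (Q2 + ca))
  expect_true(all(tau > 0))
})

test_that("all-zero fluxes freeze the calcium pools", {
  p <- calcium_params(nu_PMCA = 0, nu_SERCA = 0, nu_IP3R = 0,
                      nu_INleak = 0, nu_ERleak = 0)
  d <- calcium_rhs(c(Ca_i = 0.3, Ca_ER = 8, h_IP3R = 0.6), p, I_NMDA = 0)
  expect_equal(unname(d[c("Ca_i", "Ca_ER")]), c(0, 0))
})

test_that("the closed-cell combination Ca_i/f_c + Ca_ER/(f_ER gamma) is conserved over 10 s", {
  # no membrane fluxes: NMDA off, PMCA off, membrane leak off
  p <- calcium_params(nu_PMCA = 0, nu_INleak = 0)
  st <- c(Ca_i = 0.3, Ca_ER = 6, h_IP3R = 0.7)
  inv0 <- st[["Ca_i"]] / p$f_c + st[["Ca_ER"]] / (p$f_ER * p$gamma)
  dt <- 0.1                                   # ms
  for (k in seq_len(100000)) {                # 10 s
    st <- st + calcium_rhs(st, p, I_NMDA = 0) * dt
  }
  inv1 <- st[["Ca_i"]] / p$f_c + st[["Ca_ER"]] / (p$f_ER * p$gamma)
  expect_lt(abs(inv1 - inv0) / inv0, 1e-8)
  expect_true(st[["Ca_i"]] >= 0 && st[["Ca_ER"]] >= 0)
})

test_that("at a root-found steady state the ER fluxes balance", {
  # a tonic inward NMDA current balances the net membrane efflux, as in
  # the coupled model's resting condition
  p <- calcium_params()
  I_tonic <- -0.02
  f <- function(x) unname(calcium_rhs(c(Ca_i = abs(x[1]), Ca_ER = abs(x[2]),
                                        h_IP3R = x[3]), p,
                                      I_NMDA = I_tonic))
  x0 <- c(Ca_i = 0.1, Ca_ER = 5, h_IP3R = 0.7)
  for (k in seq_len(100000)) x0 <- x0 + calcium_rhs(x0, p, I_tonic) * 0.1
  sol <- list(x = newton_root(f, unname(x0)))
  expect_lt(max(abs(f(sol$x))), 1e-10)
  st <- c(Ca_i = abs(sol$x[1]), Ca_ER = abs(sol$x[2]), h_IP3R = sol$x[3])
  J_SERCA <- pump_flux(st[["Ca_i"]], p$nu_SERCA, p$K_SERCA, p$iota)
  J_IP3R <- ip3r_flux(st, p)
  J_ERleak <- p$nu_ERleak * (st[["Ca_ER"]] - st[["Ca_i"]])
  expect_equal(J_SERCA, J_IP3R + J_ERleak, tolerance = 1e-6)
})

test_that("an NMDA current pulse produces a calcium transient that rises and recovers", {
  p <- calcium_params()
  st <- c(Ca_i = 0.1, Ca_ER = 8, h_IP3R = 0.8)
  # settle to baseline first
  for (k in seq_len(50000)) st <- st + calcium_rhs(st, p, 0) * 0.1
  base <- st[["Ca_i"]]
  trace <- numeric(200000)
  for (k in seq_len(200000)) {                 # 20 s, pulse in first 200 ms
    I <- if (k <= 2000) -5 else 0              # inward current pulse
    st <- st + calcium_rhs(st, p, I) * 0.1
    trace[k] <- st[["Ca_i"]]
  }
  peak <- max(trace)
  expect_gt(peak, base * 1.5)                  # clear transient
  expect_lt(abs(trace[length(trace)] - base), 0.1 * (peak - base))
  expect_true(all(trace >= 0))
})

test_that("calcium stays non-negative under stiff random parameter draws", {
  set.seed(7)
  for (i in 1:5) {
    p <- calcium_params(nu_PMCA = runif(1, 50, 300),
                        nu_SERCA = runif(1, 0.5, 5),
                        nu_IP3R = runif(1, 2, 20),
                        nu_ERleak = runif(1, 0.05, 0.5),
                        IP3 = runif(1, 0.1, 0.8))
    st <- c(Ca_i = runif(1, 0.05, 1), Ca_ER = runif(1, 2, 20),
            h_IP3R = runif(1, 0.2, 0.9))
    for (k in seq_len(20000)) st <- st + calcium_rhs(st, p, 0) * 0.1
    expect_true(all(st[c("Ca_i", "Ca_ER")] >= 0))
    expect_true(st[["h_IP3R"]] >= 0 && st[["h_IP3R"]] <= 1)
  }
})
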
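test_that("gate steady state is the logistic with midpoint, saturation and unit-slope values", {
  expect_equal(gate_steady_state(-40, -40, 3), 0.5)
  expect_equal(gate_steady_state(-40, -40, -5), 0.5)
  expect_equal(gate_steady_state(1e4, -40, 3), 1)
  expect_equal(gate_steady_state(-1e4, -40, 3), 0)
  # V = V_half + slope gives 1/(1 + e^-1)
  expect_equal(gate_steady_state(-37, -40, 3), 1 / (1 + exp(-1)))
  expect_error(gate_steady_state(-40, -40, 0), "slope")
  # strictly monotone increasing for positive slope
  v <- seq(-100, 40, by = 0.5)
  expect_true(all(diff(gate_steady_state(v, -40, 3)) > 0))
})

test_that("magnesium block matches its algebraic reductions", {
  expect_equal(mg_block(-55, 0), 1.0)
  expect_equal(mg_block(60, 0), 1.0)
  expect_equal(mg_block(0, 1.5), 3.57 / (3.57 + 1.5))
  expect_equal(mg_block(-1e4, 2), 0)
  v <- seq(-90, 30, by = 1)
  expect_true(all(diff(mg_block(v, 1)) > 0))
  expect_error(mg_block(0, -1), "Mg_out")
})

test_that("ionic currents vanish at zero driving force and halve at SK half-activation", {
  p <- biophys_params()
  s <- biophys_state(V_S = p$V_Na, V_D = -70, params = p)
  expect_equal(ionic_currents(s, p)$I_Na_S, 0)
  s2 <- biophys_state(V_S = -65, V_D = -65, params = p, Ca_i = p$k_Ca)
  cur <- ionic_currents(s2, p)
  expect_equal(cur$I_SK, 0.5 * p$g_SK * (-65 - p$V_K))
  expect_equal(cur$I_coupling_S, 0)
  expect_equal(cur$I_coupling_D, 0)
})

test_that("the membrane drift has gate fixed points and is linear in I_app", {
  p <- biophys_params()
  st <- biophys_state(V_S = -62, V_D = -58, params = p)  # gates at steady state
  d <- biophys_rhs(st, p)
  expect_equal(unname(d[c("n_S", "n_D", "h_D", "p_D")]), rep(0, 4),
               tolerance = 1e-12)
  p2 <- biophys_params(I_app = 2 * p$I_app)
  d2 <- biophys_rhs(st, p2)
  expect_equal(d2[["V_S"]] - d[["V_S"]], p$I_app / p$C_m)
  d2[["V_S"]] <- d[["V_S"]]
  expect_equal(unname(d2), unname(d))
  expect_error(biophys_rhs(replace(unclass(st), 1, NaN), p), "finite")
})

test_that("a root-found equilibrium annihilates the full drift", {
  # subthreshold current, constant tonic glutamate: a resting state at
  # which every one of the fourteen derivatives vanishes
  p <- biophys_params(I_app = 2)
  p$noise$sigma_eta <- 0
  glu0 <- 30
  f <- function(x) {
    x[12:13] <- abs(x[12:13])   # keep the root search in the valid cone
    st <- setNames(x, c("V_S", "V_D", "n_S", "n_D", "h_D", "p_D",
                        "C0", "C1", "C2", "O", "D", "Ca_i", "Ca_ER",
                        "h_IP3R"))
    unname(biophys_rhs(st, p, I_syn = 0, glu = glu0))
  }
  # the Markov block conserves probability, which makes the plain Jacobian
  # singular; swap one occupancy equation for the conservation constraint
  g <- function(x) {
    r <- f(x)
    r[11] <- sum(x[7:11]) - 1
    r
  }
  # integrate close to rest under the same constant drive, then polish
  st <- unname(unclass(biophys_state(V_S = -72, V_D = -72, params = p)))
  nm <- c("V_S", "V_D", "n_S", "n_D", "h_D", "p_D", "C0", "C1", "C2",
          "O", "D", "Ca_i", "Ca_ER", "h_IP3R")
  for (k in seq_len(20000))    # 0.2 s at 0.01 ms: fast variables settle
    st <- st + unname(biophys_rhs(setNames(st, nm), p, 0, glu0)) * 0.01
  sol <- newton_root(g, st)
  expect_lt(max(abs(f(sol))), 1e-9)
})

test_that("with SK and NMDA conductances removed the voltages ignore the calcium state", {
  p <- biophys_params(g_SK = 0, g_NMDA = 0)
  p$noise$sigma_eta <- 0
  s1 <- biophys_state(params = p, Ca_i = 0.05, Ca_ER = 10, h_IP3R = 0.8)
  s2 <- biophys_state(params = p, Ca_i = 2.5, Ca_ER = 40, h_IP3R = 0.2)
  t1 <- simulate_biophys(p, duration = 0.3, seed = 1, state0 = s1,
                         stochastic_glu = FALSE)
  t2 <- simulate_biophys(p, duration = 0.3, seed = 1, state0 = s2,
                         stochastic_glu = FALSE)
  expect_identical(t1$values$V_S, t2$values$V_S)
  expect_identical(t1$values$V_D, t2$values$V_D)
})

test_that("gating variables never leave [0,1] along a spiking trajectory", {
  p <- biophys_params()
  p$noise$sigma_eta <- 0
  tr <- simulate_biophys(p, duration = 1, dt = 1e-4, seed = 1,
                         record_vars = NULL)
  g <- as.matrix(tr$values[, c("n_S", "n_D", "h_D", "p_D")])
  expect_true(all(g >= 0 & g <= 1))
})

test_that("the drift is reproducible bit-for-bit", {
  p <- biophys_params()
  st <- biophys_state(params = p)
  expect_identical(biophys_rhs(st, p, 0.3, 12), biophys_rhs(st, p, 0.3, 12))
})

test_that("parameter validation rejects degenerate geometry and unknown names", {
  expect_error(biophys_params(kappa = 0), "kappa")
  expect_error(biophys_params(kappa = 1), "kappa")
  expect_error(biophys_params(g_SK = -1), "g_SK")
  expect_error(biophys_params(g_skk = 1), "unknown")
})
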
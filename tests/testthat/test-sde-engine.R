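test_that("the recording rate must divide the stepping rate", {
  expect_error(sim_config(dt = 1e-4, record_rate = 3000), "divide")
  cfg <- sim_config(dt = 1e-4, record_rate = 2000)
  expect_equal(cfg$decimation, 5L)
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(duration = 1, burn_in = 2), "burn_in")
})

test_that("the OU stationary variance matches sigma^2/(2 theta)", {
  theta <- 1; sigma <- 1
  cfg <- sim_config(dt = 1e-3, duration = 200, seed = 4,
                    record_rate = 1000, burn_in = 10)
  tr <- integrate_sde(function(s) c(x = -theta * s[["x"]]),
                      c(x = sigma), c(x = 0), cfg)
  v <- var(tr$values$x)
  v_true <- sigma^2 / (2 * theta)
  # effective sample size for the variance of an OU variance estimate
  n_eff <- (cfg$duration - cfg$burn_in) / (2 / theta)
  se <- v_true * sqrt(2 / n_eff)
  expect_lt(abs(v - v_true), 3 * se)
})

test_that("with zero noise the scheme is forward Euler with first-order error", {
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(dt) {
    cfg <- sim_config(dt = dt, duration = 1, seed = 1, record_rate = 1 / dt)
    tr <- integrate_sde(function(s) c(x = -s[["x"]]), c(x = 0), c(x = 1), cfg)
    abs(tail(tr$values$x, 1) - exp(-1))
  }, numeric(1))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.1)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.1)
})

test_that("identical seeds give identical trajectories, for the generic and both model steppers", {
  cfg <- sim_config(dt = 1e-3, duration = 2, seed = 9, record_rate = 1000)
  t1 <- integrate_sde(function(s) c(x = -s[["x"]]), c(x = 1), c(x = 0), cfg)
  t2 <- integrate_sde(function(s) c(x = -s[["x"]]), c(x = 1), c(x = 0), cfg)
  expect_identical(t1$values$x, t2$values$x)
  h1 <- simulate_hr(hr_params(sigma_V = 0.2), duration = 1, seed = 3)
  h2 <- simulate_hr(hr_params(sigma_V = 0.2), duration = 1, seed = 3)
  expect_identical(h1$values, h2$values)
  p <- biophys_params()
  b1 <- simulate_biophys(p, duration = 0.2, seed = 3)
  b2 <- simulate_biophys(p, duration = 0.2, seed = 3)
  expect_identical(b1$values, b2$values)
})

test_that("decimation keeps exact sample values with no interpolation", {
  cfg_full <- sim_config(dt = 1e-3, duration = 1, seed = 2, record_rate = 1000)
  cfg_dec <- sim_config(dt = 1e-3, duration = 1, seed = 2, record_rate = 100)
  rhs <- function(s) c(x = -0.5 * s[["x"]])
  full <- integrate_sde(rhs, c(x = 1), c(x = 0.3), cfg_full)
  dec <- integrate_sde(rhs, c(x = 1), c(x = 0.3), cfg_dec)
  expect_identical(dec$values$x, full$values$x[seq(10, 1000, by = 10)])
})

test_that("the strong error against a fine-step reference shrinks with dt", {
  # one OU path under a shared Brownian refinement
  theta <- 1; sigma <- 1; T_end <- 1
  dt_f <- 1e-4; n_f <- T_end / dt_f
  set.seed(21)
  dW <- rnorm(n_f, sd = sqrt(dt_f))
  euler_path <- function(fac) {
    dt <- dt_f * fac
    x <- 1
    for (k in seq_len(n_f / fac)) {
      dWk <- sum(dW[((k - 1) * fac + 1):(k * fac)])
      x <- x - theta * x * dt + sigma * dWk
    }
    x
  }
  ref <- euler_path(1)
  errs <- vapply(c(100, 20, 4), function(f) abs(euler_path(f) - ref),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  # convergence at least as fast as sqrt(dt)
  expect_gt(log(errs[1] / errs[3]) / log(5), 0.5)
})

test_that("non-finite states abort with a step index", {
  cfg <- sim_config(dt = 0.5, duration = 10, seed = 1, record_rate = 2)
  expect_error(
    integrate_sde(function(s) c(x = s[["x"]]^3), c(x = 0), c(x = 3), cfg),
    "step")
})
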
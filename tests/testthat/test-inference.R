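test_that("the weighted normalised loss vanishes iff features match and unrolls per feature", {
  feats <- c(mean_fr = 20, burst_fraction = 0.4, cv_isi = 1.1)
  tgt <- feature_target(feats)
  expect_equal(fit_loss(feats, tgt)$total, 0)
  # one feature off by exactly its scale, weight w
  tgt2 <- feature_target(feats, weights = c(mean_fr = 2, burst_fraction = 1,
                                            cv_isi = 1))
  sim <- feats; sim["mean_fr"] <- feats["mean_fr"] + tgt2$scales[["mean_fr"]]
  expect_equal(fit_loss(sim, tgt2)$total, 2 / 4)
  # strictly increasing in any single deviation
  sim2 <- feats; sim2["cv_isi"] <- feats["cv_isi"] * 1.3
  sim3 <- feats; sim3["cv_isi"] <- feats["cv_isi"] * 1.6
  expect_gt(fit_loss(sim3, tgt)$total, fit_loss(sim2, tgt)$total)
  # equal weights: loss < 0.1 iff mean normalised error < 10%
  sim4 <- feats * 1.05
  expect_lt(fit_loss(sim4, tgt)$total, 0.1)
  expect_error(feature_target(c(a = 1), weights = c(a = 0)), "not all zero")
})

test_that("missing features are excluded with weight renormalisation", {
  feats <- c(mean_fr = 20, adp_v = NA_real_)
  tgt <- feature_target(c(mean_fr = 20, adp_v = -60))
  l <- fit_loss(feats, tgt)
  expect_equal(l$total, 0)
  expect_equal(names(l$per_feature), "mean_fr")
  expect_error(fit_loss(c(mean_fr = NA_real_), feature_target(c(mean_fr = 1))),
               "overlapping")
})

test_that("NSGA-II approximates the Schaffer biobjective front and respects bounds", {
  fn <- function(x) c(x[1]^2, (x[1] - 2)^2)
  res <- nsga2(fn, lower = -5, upper = 5, pop_size = 40, n_gen = 20, seed = 2)
  expect_true(all(res$pareto_X >= -5 & res$pareto_X <= 5))
  # the true Pareto set is x in [0, 2]
  expect_true(mean(res$pareto_X >= -0.1 & res$pareto_X <= 2.1) > 0.9)
  # front quality: f1 + f2 >= 2 with equality on the front
  expect_lt(min(rowSums(res$pareto_F)), 2.1)
  # reproducible per seed
  res2 <- nsga2(fn, -5, 5, pop_size = 40, n_gen = 20, seed = 2)
  expect_identical(res$pareto_X, res2$pareto_X)
})

test_that("fitting preconditions and degenerate search spaces behave", {
  tgt <- feature_target(c(mean_fr = 30, cv_isi = 1))
  expect_error(fit_model("hr_modified", hr_params(),
                         list(I_app = c(2, 3)), tgt,
                         budget = 10, pop_size = 50), "pop_size")
})

test_that("synthetic modified-HR targets are recovered within the acceptance gate", {
  theta <- list(I_app = 2.6, gamma_d = 0.1, sigma_V = 0.2)
  p_true <- do.call(hr_params, theta)
  rec <- generate_reference_recording("hr_modified", p_true, seed = 101)
  f <- trace_features(rec$trace, threshold = 0)
  target <- feature_target(f[c("mean_fr", "burst_fraction", "mean_isi",
                               "median_isi", "std_isi", "cv_isi")],
                           isi_sample = diff(rec$spikes$spike_times))
  bounds <- lapply(theta, function(v) sort(c(0.8, 1.2) * v))
  fit <- fit_model("hr_modified", hr_params(), bounds, target,
                   budget = 300, pop_size = 30, seed = 5)
  expect_lt(fit$loss, 0.1)
  expect_true(fit$accepted)
  expect_gt(fit$ks$p_value, 0.05)
  # recovered parameters stay inside the box
  for (nm in names(bounds))
    expect_true(fit$par[[nm]] >= bounds[[nm]][1] &&
                  fit$par[[nm]] <= bounds[[nm]][2])
})

test_that("archive-ratio Sobol indices isolate a single active factor", {
  set.seed(3)
  n <- 800
  arch <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  arch$loss <- 0.09 * arch$a   # below threshold, depends on a only
  res <- sobol_fit_archive(arch, loss_threshold = 0.1)
  S <- setNames(res$S, res$parameter)
  expect_gt(S[["a"]], 0.9)
  expect_lt(S[["b"]], 0.05)
  expect_lt(S[["c"]], 0.05)
})

test_that("archive-ratio indices match the analytic additive decomposition", {
  set.seed(4)
  n <- 4000
  a_coef <- c(3, 2, 1)
  X <- matrix(runif(3 * n), n, 3)
  arch <- data.frame(x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  arch$loss <- (X %*% a_coef) / 100   # keep losses below the threshold
  res <- sobol_fit_archive(arch, loss_threshold = 0.1, n_bins = 12)
  S_true <- a_coef^2 / sum(a_coef^2)  # equal Var(x_i) cancels
  expect_equal(setNames(res$S, NULL), S_true, tolerance = 0.08)
  expect_lte(sum(res$S), 1.1)
  expect_error(sobol_fit_archive(data.frame(a = 1:5, loss = rep(1, 5))),
               "insufficient")
})

test_that("Saltelli indices recover the Ishigami closed form", {
  rng <- list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi))
  res <- sobol_model(ishigami, rng, n_samples = 8192, seed = 6)
  truth <- ishigami_indices()
  expect_true(all(abs(setNames(res$S, res$parameter) - truth) < 0.05))
})

test_that("degenerate Sobol problems are caught or trivially solved", {
  rng <- list(x1 = c(0, 1), x2 = c(0, 1))
  expect_error(sobol_model(function(x) 1, rng, n_samples = 128, seed = 1),
               "zero-variance")
  res <- sobol_model(function(x) x[1], rng, n_samples = 2048, seed = 1)
  S <- setNames(res$S, res$parameter)
  expect_equal(S[["x1"]], 1, tolerance = 0.05)
  expect_equal(S[["x2"]], 0, tolerance = 0.05)
})
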
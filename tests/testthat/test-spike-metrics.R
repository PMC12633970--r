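test_that("threshold detection finds constructed peaks and merges close doubles", {
  expect_equal(length(detect_spikes(bump_trace(numeric(0)))$spike_times), 0)
  expect_error(detect_spikes(data.frame(t_s = numeric(0), v = numeric(0))),
               "empty")
  two <- bump_trace(c(0.4, 0.43))
  sp <- detect_spikes(two, threshold = -30)
  expect_equal(length(sp$spike_times), 2)
  expect_equal(sp$spike_times, c(0.4, 0.43), tolerance = 2e-4)
  close_pair <- bump_trace(c(0.4, 0.4005))
  sp2 <- detect_spikes(close_pair, threshold = -30)
  expect_equal(length(sp2$spike_times), 1)
})

test_that("waveform features follow the hand geometry of a piecewise-linear spike", {
  # onset -55 at 10 ms, peak +20 at 12 ms, trough -65 at 14 ms, then flat
  fs <- 10000
  t <- seq(0, 0.05, by = 1 / fs)
  v <- rep(-70, length(t))
  seg <- function(t0, t1, v0, v1) {
    i <- which(t >= t0 & t <= t1)
    v[i] <<- v0 + (v1 - v0) * (t[i] - t0) / (t1 - t0)
  }
  seg(0.008, 0.010, -70, -55)      # slow approach to onset
  seg(0.010, 0.012, -55, 20)       # fast upstroke
  seg(0.012, 0.014, 20, -65)       # downstroke to trough
  seg(0.014, 0.020, -65, -65)      # flat after-trough: no ADP
  seg(0.020, 0.050, -65, -70)
  trace <- data.frame(t_s = t, v = v)
  sp <- detect_spikes(trace, threshold = -30)
  expect_equal(length(sp$spike_times), 1)
  ft <- extract_ap_features(trace, sp)
  expect_equal(ft$peak_v, 20, tolerance = 1e-6)
  expect_equal(ft$trough_v, -65, tolerance = 1e-6)
  expect_equal(ft$threshold_v, -55, tolerance = 4)   # dV/dt onset near -55
  expect_equal(ft$upstroke_v, (ft$threshold_v + ft$peak_v) / 2)
  expect_equal(ft$downstroke_v, (20 + -65) / 2, tolerance = 2)
  expect_true(is.na(ft$adp_v))                       # monotone post-trough
})

test_that("an afterdepolarisation bump is picked up and clipped spikes are dropped", {
  fs <- 10000
  t <- seq(0, 0.06, by = 1 / fs)
  v <- -70 + 90 * exp(-(t - 0.03)^2 / (2 * 0.0004^2)) +
    8 * exp(-(t - 0.0345)^2 / (2 * 0.0008^2))        # spike then ADP bump
  trace <- data.frame(t_s = t, v = v)
  sp <- detect_spikes(trace, threshold = -30)
  ft <- extract_ap_features(trace, sp)
  expect_false(is.na(ft$adp_v))
  expect_gt(ft$adp_v, ft$trough_v)
  # a spike at the very edge of the trace is excluded
  edge <- data.frame(t_s = t, v = -70 + 90 * exp(-(t - 0.001)^2 / (2 * 0.0004^2)))
  spe <- detect_spikes(edge, threshold = -30)
  expect_equal(nrow(extract_ap_features(edge, spe)), 0)
})

test_that("ISI distribution machinery: Scott bandwidth, clock trains, bimodal mixtures", {
  x <- rnorm(100)
  expect_equal(bw_scott(x), sd(x) * 100^(-1 / 5))
  clock <- spike_train(seq(0.1, 4.9, by = 0.1), duration = 5)
  d <- isi_distribution(clock, n_boot = 0)
  expect_equal(unique(round(d$isis, 10)), 0.1)
  expect_equal(d$kde$x[which.max(d$kde$y)], 0.1, tolerance = 5e-3)
  set.seed(2)
  isis <- c(rnorm(150, 5e-3, 5e-4), rnorm(150, 0.1, 0.01))
  mix <- spike_train(cumsum(sample(isis)), duration = sum(isis) + 1)
  dm <- isi_distribution(mix, n_boot = 0)
  n_modes <- sum(diff(sign(diff(dm$kde$y))) == -2)
  expect_gte(n_modes, 2)
  lone <- spike_train(0.5, duration = 1)
  expect_error(isi_distribution(lone), "2 spikes")
})

test_that("the bootstrap band is finite and non-negative on a rich train", {
  set.seed(3)
  st <- random_spike_train(400)
  d <- isi_distribution(st, n_boot = 50, segment = 4)
  expect_true(all(is.finite(d$kde_sd)))
  expect_true(all(d$kde_sd >= 0))
})

test_that("burst partition reproduces the hand-enumerated example and its edge cases", {
  st <- spike_train(c(0, 5, 10, 100, 200) / 1000, duration = 0.3)
  bp <- burst_partition(st, 0.012)
  expect_equal(bp$burst_fraction, 0.6)
  expect_equal(bp$labels, c("burst", "burst", "burst", "isolated", "isolated"))
  expect_equal(bp$bursts, list(1:3))
  all_long <- spike_train(seq(0, 2, by = 0.1), duration = 2.5)
  expect_equal(burst_partition(all_long)$burst_fraction, 0)
  all_short <- spike_train(seq(0, 0.05, by = 0.005), duration = 0.2)
  bp2 <- burst_partition(all_short)
  expect_equal(bp2$burst_fraction, 1)
  expect_equal(length(bp2$bursts), 1)
})

test_that("burst partition agrees with brute-force run enumeration on 1000 random trains", {
  set.seed(11)
  for (i in 1:1000) {
    st <- random_spike_train(sample(2:40, 1), p_short = runif(1))
    thr <- runif(1, 0.005, 0.05)
    bp <- burst_partition(st, thr)
    or <- oracle_burst_fraction(st$spike_times, thr)
    expect_identical(bp$burst_fraction, or$burst_fraction)
    expect_identical(as.integer(bp$burst_sizes), as.integer(or$sizes))
  }
})

test_that("burst fraction is monotone non-decreasing in the ISI threshold", {
  set.seed(12)
  st <- random_spike_train(300)
  thrs <- seq(0.002, 0.1, by = 0.002)
  bf <- vapply(thrs, function(th) burst_partition(st, th)$burst_fraction,
               numeric(1))
  expect_true(all(diff(bf) >= 0))
})

test_that("summary statistics match hand arithmetic", {
  st <- spike_train(c(1, 2.5, 4), duration = 5)
  s <- spike_summary(st)
  expect_equal(s$mean_fr, 0.6)
  st2 <- spike_train(c(0.1, 0.11, 0.13), duration = 1)   # ISIs 10, 20 ms
  s2 <- spike_summary(st2)
  expect_equal(s2$mean_isi, 0.015)
  expect_equal(s2$median_isi, 0.015)
  expect_equal(s2$std_isi, sd(c(0.01, 0.02)))
  clock <- spike_train(seq(0.1, 4.9, by = 0.1), duration = 5)
  expect_equal(spike_summary(clock)$cv_isi, 0)
})

test_that("the two-sample KS statistic matches the exhaustive ECDF oracle", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 20, 30))$D, 1)
  set.seed(13)
  for (i in 1:100) {
    x <- rnorm(sample(3:30, 1))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(x, y)$D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("features are stable across a doubled-then-decimated sampling rate", {
  p <- hr_params()
  tr20 <- simulate_hr(p, duration = 5, seed = 6, record_rate = 20000)
  v20 <- trace_df(tr20, "V")
  v10 <- v20[seq(2, nrow(v20), by = 2), ]
  s20 <- detect_spikes(v20, threshold = 0)
  s10 <- detect_spikes(v10, threshold = 0)
  expect_equal(length(s20$spike_times), length(s10$spike_times))
  expect_lt(max(abs(s20$spike_times - s10$spike_times)), 1e-4 + 1e-9)
})
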
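test_that("RT draws are reproducible, positive, and match closed-form quantiles", {
  dist <- list(shift = 0.2, meanlog = log(0.6), sdlog = 0.35)

  # degenerate distribution: all mass at shift + median
  d0 <- list(shift = 0.3, meanlog = log(0.5), sdlog = 0)
  expect_equal(draw_rts(5, d0, seed = 1), rep(0.8, 5))

  # empirical quantiles converge to the shifted-lognormal quantiles
  r <- draw_rts(10000, dist, seed = 123)
  expect_true(all(r > dist$shift))
  for (p in c(0.1, 0.5, 0.9)) {
    analytic <- dist$shift + qlnorm(p, dist$meanlog, dist$sdlog)
    expect_lt(abs(unname(quantile(r, p)) - analytic) / analytic, 0.02)
  }

  # determinism and error paths
  expect_identical(draw_rts(50, dist, seed = 7), draw_rts(50, dist, seed = 7))
  expect_error(draw_rts(0, dist), "positive count")
  expect_error(draw_rts(10, list(shift = -0.1, meanlog = 0, sdlog = 0.3)),
               "invalid RT distribution")
})

test_that("SR trials are the linear sum of RT-invariant S and R kernels", {
  fs <- 100
  sk <- hanning_kernel(0.3, 0.6, 1, fs)
  rk <- hanning_kernel(-0.2, 0.6, 0.8, fs)
  zero_rk <- waveform_kernel(rk$lags, rep(0, length(rk$lags)), fs)

  # additive identity: all-zero R kernel leaves the S kernel
  tr <- make_sr_trial(0.7, sk, zero_rk, fs)
  s_idx <- round(sk$lags * fs) - round(tr$offset * fs) + 1
  expect_equal(tr$values[s_idx], sk$values)

  # disjoint supports: max equals the larger kernel max
  tr2 <- make_sr_trial(2.0, sk, rk, fs)
  expect_equal(max(tr2$values), max(max(sk$values), max(rk$values)))

  # overlapping supports: sample-by-sample against direct addition
  rt <- 0.45
  tr3 <- make_sr_trial(rt, sk, rk, fs)
  lo <- round(tr3$offset * fs)
  direct <- numeric(length(tr3$values))
  direct[round(sk$lags * fs) - lo + 1] <-
    direct[round(sk$lags * fs) - lo + 1] + sk$values
  r_idx <- round(rt * fs) + round(rk$lags * fs) - lo + 1
  direct[r_idx] <- direct[r_idx] + rk$values
  expect_equal(tr3$values, direct)

  # the S and R contributions each peak at an RT-independent amplitude
  # (scenario-A ground truth); isolate each via a zeroed partner kernel
  zero_sk <- waveform_kernel(sk$lags, rep(0, length(sk$lags)), fs)
  s_peaks <- vapply(c(0.5, 0.8, 1.3), function(rt)
    max(make_sr_trial(rt, sk, zero_rk, fs)$values), numeric(1))
  r_peaks <- vapply(c(0.5, 0.8, 1.3), function(rt)
    max(make_sr_trial(rt, zero_sk, rk, fs)$values), numeric(1))
  expect_equal(s_peaks, rep(max(sk$values), 3))
  expect_equal(r_peaks, rep(max(rk$values), 3))

  expect_error(make_sr_trial(0.001, sk, rk, fs), "shorter than one sample")
})

test_that("ramp trials reach the bound at response with the stated slope", {
  fs <- 100
  # constant bound: value at response = b0, slope = b0 / (rt - onset)
  tr <- make_ramp_trial(0.5, 0.1, bound_constant(1), 0.1, fs)
  expect_equal(attr(tr, "amp_at_response"), 1)
  expect_equal(attr(tr, "slope"), 1 / 0.4)
  expect_equal(tr$values[round(0.5 * fs) + 1], 1)
  expect_equal(tr$values[round(0.1 * fs) + 1], 0)

  # trajectory at response equals the bound function, any config
  b <- bound_collapsing(1, 0.4, 1)
  for (rt in c(0.41, 0.77, 1.2)) {
    tr <- make_ramp_trial(rt, 0.1, b, 0.1, fs)
    rt_g <- round(rt * fs) / fs
    expect_equal(tr$values[round(rt_g * fs) + 1], b(rt_g), tolerance = 1e-12)
  }

  # collapsing bound: amplitude and slope strictly decrease with RT
  rts <- c(0.5, 0.8, 1.1, 1.4)
  amps <- vapply(rts, function(rt)
    attr(make_ramp_trial(rt, 0.1, b, 0.1, fs), "amp_at_response"), numeric(1))
  slopes <- vapply(rts, function(rt)
    attr(make_ramp_trial(rt, 0.1, b, 0.1, fs), "slope"), numeric(1))
  expect_true(all(diff(amps) < 0))
  expect_true(all(diff(slopes) < 0))

  expect_error(make_ramp_trial(0.05, 0.1, b, 0.1, fs), "must exceed")
})

test_that("noiseless diffusion reduces to a deterministic ramp", {
  # decision time = bound / drift, exact up to one integration step
  tr <- simulate_ddm_trial(drift = 2, noise_sd = 0, bound = bound_constant(1),
                           dt = 0.001, pre_ea_delay = 0, post_ea_delay = 0)
  expect_lt(abs(tr$decision_time - 0.5), 0.001 + 1e-12)
  expect_equal(tr$rt, 0.5)

  # with noise 0 the trajectory equals the RAMP trajectory with
  # onset_delay = pre_ea_delay
  tr2 <- simulate_ddm_trial(drift = 1, noise_sd = 0, bound = bound_constant(0.5),
                            dt = 0.001, pre_ea_delay = 0.1, post_ea_delay = 0,
                            fs = 100)
  rp <- make_ramp_trial(tr2$rt, 0.1, bound_constant(0.5), 0.1, 100)
  expect_equal(tr2$segment$values, rp$values, tolerance = 1e-12)
})

test_that("diffusion first-passage times match the single-boundary mean", {
  # Wald mean first-passage time for drift mu to bound b is b / mu
  set.seed(42)
  dts <- replicate(10000, simulate_ddm_trial(1, 1, bound_constant(1),
                                             dt = 0.001)$decision_time)
  expect_lt(abs(mean(dts) - 1), 0.05)
})

test_that("non-crossing diffusion paths raise a diagnostic error", {
  set.seed(9)
  expect_error(
    simulate_ddm_trial(drift = -1, noise_sd = 0.01, bound = bound_constant(5),
                       dt = 0.01, max_decision_time = 0.5, max_resample = 2),
    "failed to reach the bound")
})

test_that("assembled recordings are the exact superposition of trial segments", {
  # single noise-free trial: the recording restricted to the trial support
  # equals the per-trial segment exactly
  cfg1 <- scenario_config("RAMP", n_trials = 1, seed = 4)
  sim1 <- assemble_recording(cfg1)
  seg <- make_ramp_trial(sim1$events$rt[1], cfg1$ramp$onset_delay, cfg1$bound,
                         cfg1$ramp$post_response_decay, cfg1$fs)
  i0 <- sample_index(sim1$events$stim_onset[1] + seg$offset, cfg1$fs)
  expect_equal(sim1$recording$samples[i0:(i0 + length(seg$values) - 1)],
               seg$values)
  expect_true(all(sim1$recording$samples[seq_len(i0 - 1)] == 0))

  # determinism: same config, two calls, bit-identical
  cfg <- scenario_config("SR", n_trials = 40, seed = 99, sensor_noise_sd = 0.1)
  a <- assemble_recording(cfg)
  b <- assemble_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)

  # energy bookkeeping: noise-free recording equals a brute-force
  # re-placement of the per-trial segments
  cfg2 <- scenario_config("SR", n_trials = 100, seed = 12)
  sim2 <- assemble_recording(cfg2)
  segs <- lapply(sim2$events$rt, make_sr_trial, s_kernel = cfg2$s_kernel,
                 r_kernel = cfg2$r_kernel, fs = cfg2$fs)
  brute <- brute_force_place(segs, sim2$events$stim_onset,
                             length(sim2$recording$samples), cfg2$fs)
  expect_equal(sim2$recording$samples, brute)
  # and the tracked S/R parts sum to the recording
  expect_equal(sim2$parts$S$samples + sim2$parts$R$samples,
               sim2$recording$samples)
})

test_that("event tables enforce their temporal invariants", {
  expect_error(event_table(c(1, 2), c(0.9, 2.5)), "response must follow")
  expect_error(event_table(c(2, 1), c(2.5, 1.5)), "non-decreasing")
  ev <- event_table(c(1, 3), c(1.7, 3.9))
  expect_equal(ev$rt, c(0.7, 0.9))
  expect_true(all(ev$rt_category == "unassigned"))
})
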
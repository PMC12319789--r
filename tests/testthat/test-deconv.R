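test_that("median RT split assigns categories with the documented tie rule", {
  ev <- event_table(c(1, 4, 7, 10), c(1.4, 4.6, 7.8, 11))  # RTs .4 .6 .8 1.0
  ev <- assign_rt_categories(ev)
  expect_equal(as.character(ev$rt_category), c("fast", "fast", "slow", "slow"))

  # all RTs identical: no slow trial can exist
  ev2 <- event_table(c(1, 3, 5), c(1.5, 3.5, 5.5))
  expect_error(assign_rt_categories(ev2), "degenerate")
  expect_error(assign_rt_categories(ev2[1, ]), "at least 2 trials")

  # odd n: the median trial goes to fast (direct sort oracle)
  rts <- draw_rts(1001, seed = 77)
  stim <- cumsum(rep(3, 1001))
  ev3 <- assign_rt_categories(event_table(stim, stim + rts))
  expect_equal(sum(ev3$rt_category == "fast"), 501L)
  expect_equal(sum(ev3$rt_category == "slow"), 500L)
  expect_equal(as.character(ev3$rt_category[which(rts == median(rts))]), "fast")
})

test_that("time-expanded designs have the 0/1 indicator structure", {
  fs <- 100
  # one stimulus event at sample 100, S window of three lags
  ev <- event_table(0.99, 0.99 + 0.5)
  spec <- design_spec(fs, s_window = c(0, 0.02), r_window = c(-0.1, 0))
  d <- build_design(ev, spec, 300)
  s_cols <- d$colmap$col[d$colmap$event == "S"]
  Xs <- as.matrix(d$X[, s_cols])
  expect_equal(sum(Xs != 0), 3)
  expect_equal(which(Xs[, 1] == 1), 100L)
  expect_equal(which(Xs[, 2] == 1), 101L)
  expect_equal(which(Xs[, 3] == 1), 102L)
  expect_true(all(d$X@x == 1))
  expect_equal(ncol(d$X), 3L + 11L)

  # two events closer than the window length: overlapping rows carry two 1s
  # in different columns (direct construction oracle)
  ev2 <- event_table(c(1, 1.05), c(1.5, 1.6))
  d2 <- build_design(ev2, design_spec(fs, s_window = c(0, 0.1),
                                      r_window = c(-0.05, 0)), 300)
  s_cols2 <- d2$colmap$col[d2$colmap$event == "S"]
  Xs2 <- as.matrix(d2$X[, s_cols2])
  overlap_rows <- 106:111  # samples covered by both events' S windows
  expect_true(all(rowSums(Xs2[overlap_rows, ]) == 2))
  oracle <- matrix(0, 300, 11)
  for (e in c(101, 106)) for (l in 0:10) oracle[e + l, l + 1] <- oracle[e + l, l + 1] + 1
  expect_equal(unname(Xs2), oracle)

  # empty event table is refused
  expect_error(build_design(event_table(numeric(0), numeric(0)), spec, 300),
               "empty")
  # events whose window exceeds the recording edge are refused
  expect_error(build_design(ev, spec, 100), "outside the recording")
})

test_that("the sparse fit equals exact recovery and the dense OLS oracle", {
  # exact linear recovery: recording constructed as design x known betas
  inst <- random_small_instance(301)
  beta0 <- rnorm(ncol(inst$design$X))
  rec <- continuous_recording(as.numeric(inst$design$X %*% beta0), 100)
  fit <- deconv_fit(rec, inst$events, design = inst$design)
  expect_equal(fit$coefficients, beta0, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)

  # tiny noisy instance: betas equal the dense normal-equations solution
  inst2 <- random_small_instance(302)
  fit2 <- deconv_fit(inst2$recording, inst2$events, design = inst2$design)
  oracle <- dense_ols(inst2$design$X, inst2$recording$samples)
  expect_lt(max(abs(fit2$coefficients - oracle)) / max(abs(oracle)), 1e-8)
})

test_that("rank-deficient designs are refused with a collinearity message", {
  # identical RTs make R-lag columns duplicates of shifted S-lag columns
  stim <- 2 + (0:39) * 3
  ev <- event_table(stim, stim + 0.7)
  set.seed(5)
  rec <- continuous_recording(rnorm(round((max(stim) + 3) * 100)), 100)
  expect_error(suppressWarnings(deconv_fit(rec, ev, design_spec(fs = 100))),
               "rank deficient")
})

test_that("prediction, subtraction and residuals decompose the recording", {
  cfg <- scenario_config("SR", n_trials = 60, seed = 8)
  sim <- assemble_recording(cfg)
  ev <- assign_rt_categories(sim$events)
  fit <- deconv_fit(sim$recording, ev)

  # OLS decomposition: prediction(all) + residual == recording, sample-exact
  full <- predict(fit)
  expect_equal(full$samples + residuals(fit), sim$recording$samples,
               tolerance = 1e-12)

  # empty subset -> all-zero signal; unknown predictor -> error
  expect_true(all(predict(fit, character(0))$samples == 0))
  expect_error(predict(fit, "Q"), "unknown predictor")

  # noise-free scenario A: the S prediction equals the true summed S
  # contributions (ground-truth bookkeeping from the simulator)
  s_pred <- predict(fit, "S")
  expect_equal(s_pred$samples, sim$parts$S$samples, tolerance = 1e-8)

  # subtracting zero is the identity; subtracting the full prediction
  # leaves the fit's residual variance
  zero <- continuous_recording(numeric(length(sim$recording$samples)), cfg$fs)
  expect_equal(subtract_component(sim$recording, zero)$samples,
               sim$recording$samples)
  resid_rec <- subtract_component(sim$recording, full)
  expect_equal(var(resid_rec$samples), fit$sigma2, tolerance = 1e-12)
  expect_error(subtract_component(sim$recording,
                                  continuous_recording(1:5, cfg$fs)),
               "differ in length")
})

test_that("residual fraction is ~0 for generated data and ~1 for pure noise", {
  inst <- random_small_instance(99)
  beta0 <- rnorm(ncol(inst$design$X))
  rec <- continuous_recording(as.numeric(inst$design$X %*% beta0), 100)
  fit <- deconv_fit(rec, inst$events, design = inst$design)
  expect_lt(residual_fraction(rec, fit), 1e-12)

  # recording with no event-locked structure: nothing real to explain
  cfg <- scenario_config("SR", n_trials = 80, seed = 21)
  sim <- assemble_recording(cfg)
  set.seed(31)
  noise <- continuous_recording(rnorm(length(sim$recording$samples)), cfg$fs)
  fitn <- deconv_fit(noise, sim$events)
  expect_gt(residual_fraction(noise, fitn), 0.9)
  expect_lt(residual_fraction(noise, fitn), 1.0)

  expect_error(residual_fraction(continuous_recording(rep(1, 10), 100), fit),
               "zero variance")
})

test_that("estimates are invariant to trial order in the event table", {
  cfg <- scenario_config("SR", n_trials = 50, seed = 14)
  sim <- assemble_recording(cfg)
  ev <- assign_rt_categories(sim$events)
  fit <- deconv_fit(sim$recording, ev,
                    design_spec(fs = cfg$fs, r_scheme = "by_rt_category"))
  set.seed(2)
  shuffled <- ev[sample(nrow(ev)), ]
  fit2 <- deconv_fit(sim$recording, shuffled,
                     design_spec(fs = cfg$fs, r_scheme = "by_rt_category"))
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-10)
})

test_that("by-category schemes demand assigned, non-empty categories", {
  cfg <- scenario_config("SR", n_trials = 20, seed = 3)
  sim <- assemble_recording(cfg)
  expect_error(deconv_fit(sim$recording, sim$events,
                          design_spec(fs = cfg$fs, s_scheme = "by_rt_category")),
               "assign_rt_categories")
})
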
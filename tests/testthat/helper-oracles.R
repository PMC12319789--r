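# Independent oracles used across the suite.

# Dense least squares via QR, independent of the sparse solver path.
dense_ols <- function(X, y) qr.solve(as.matrix(X), y)

# Brute-force placement: add each trial's segment into a zero signal by
# direct index arithmetic (independent of assemble_recording internals).
brute_force_place <- function(segments, stim_onset, n_samples, fs) {
  out <- numeric(n_samples)
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    i0 <- as.integer(round((stim_onset[i] + seg$offset) * fs)) + 1L
    idx <- i0:(i0 + length(seg$values) - 1L)
    out[idx] <- out[idx] + seg$values
  }
  out
}

# Random small deconvolution instance for solver-oracle checks: a short
# recording with a handful of jittered stimulus/response events and narrow
# expansion windows.
random_small_instance <- function(seed) {
  set.seed(seed)
  fs <- 100
  n_ev <- sample(2:6, 1)           # trials (2 events each, <= 12 events)
  rts <- runif(n_ev, 0.25, 0.8)
  itis <- runif(n_ev, 0.8, 1.6)
  stim <- 1 + cumsum(c(0, (rts + itis)[-n_ev]))
  stim <- round(stim * fs) / fs
  rts <- round(rts * fs) / fs
  events <- event_table(stim, stim + rts)
  n_samples <- as.integer(round((max(events$resp_onset) + 1) * fs))
  spec <- design_spec(fs, s_window = c(-0.1, 0.4), r_window = c(-0.3, 0.1))
  design <- build_design(events, spec, n_samples)
  y <- rnorm(n_samples)
  list(events = events, design = design, spec = spec,
       recording = continuous_recording(y, fs), n_samples = n_samples)
}
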
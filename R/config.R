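#' Full parameterization of one simulated ground-truth world
#'
#' A scenario config fixes everything a simulation run depends on: the
#' generative scenario, trial count, sampling rate, RT and inter-trial
#' interval distributions, scenario-specific parameters, sensor noise and the
#' RNG seed. Given a config, [assemble_recording()] is a pure function: the
#' same config always yields bit-identical output.
#'
#' Scenarios:
#' \describe{
#'   \item{SR}{timescale-invariant stimulus (S) and response (R) component
#'     kernels, RT-independent amplitudes, overlapping according to RT.}
#'   \item{RAMP}{a single accumulation-to-bound ramp interposed between
#'     stimulus and response (no S or R components).}
#'   \item{DDM}{a diffusion-type evidence-accumulation trajectory with
#'     jittered pre- and post-accumulation non-decision delays.}
#' }
#'
#' @param scenario `"SR"`, `"RAMP"` or `"DDM"`.
#' @param n_trials number of trials.
#' @param fs sampling rate in Hz.
#' @param rt shifted-lognormal RT parameters (SR/RAMP scenarios): list
#'   `shift`, `meanlog`, `sdlog`. DDM RTs emerge from the process instead.
#' @param iti uniform inter-trial interval (response to next stimulus):
#'   list `min`, `max` in seconds.
#' @param s_kernel,r_kernel SR scenario component kernels
#'   ([waveform_kernel()]); defaults peak 300 ms post-stimulus and 200 ms
#'   pre-response.
#' @param ramp RAMP parameters: list `onset_delay`, `post_response_decay`
#'   (seconds).
#' @param bound decision bound (`bound_fun`), used by RAMP and DDM.
#' @param ddm DDM parameters: list `drift`, `noise_sd`, `dt`, `pre_mean`,
#'   `pre_sd`, `post_mean`, `post_sd` (non-decision delay means/SDs in
#'   seconds), `max_decision_time`, `max_resample`, `post_response_decay`.
#' @param sensor_noise_sd white Gaussian sensor noise SD (0 = noise free).
#' @param pad silent padding in seconds before the first stimulus and after
#'   the last response (must cover every analysis window).
#' @param seed integer RNG seed; fully determines every draw.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("SR", "RAMP", "DDM"),
                            n_trials = 500, fs = 100,
                            rt = list(shift = 0.2, meanlog = log(0.6), sdlog = 0.35),
                            iti = list(min = 1.5, max = 2.5),
                            s_kernel = NULL, r_kernel = NULL,
                            ramp = list(onset_delay = 0.1, post_response_decay = 0.1),
                            bound = bound_collapsing(1, 0.4, 1),
                            ddm = list(drift = 1, noise_sd = 0.3, dt = 0.001,
                                       pre_mean = 0.15, pre_sd = 0.035,
                                       post_mean = 0.15, post_sd = 0.035,
                                       max_decision_time = 10, max_resample = 10,
                                       post_response_decay = 0.1),
                            sensor_noise_sd = 0, pad = 1.5, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_trials < 1) stop("'n_trials' must be positive")
  if (fs <= 0) stop("'fs' must be positive")
  if (iti$min <= 0 || iti$max < iti$min) stop("invalid ITI range")
  if (pad <= 0) stop("'pad' must be positive")
  if (sensor_noise_sd < 0) stop("'sensor_noise_sd' must be non-negative")
  if (scenario == "SR") {
    if (is.null(s_kernel)) s_kernel <- hanning_kernel(0.3, 0.6, 1, fs)
    if (is.null(r_kernel)) r_kernel <- hanning_kernel(-0.2, 0.6, 1, fs)
    if (s_kernel$fs != fs || r_kernel$fs != fs)
      stop("kernel fs must match config fs")
  }
  if (scenario == "RAMP") {
    if (ramp$onset_delay < 0 || ramp$post_response_decay < 0)
      stop("ramp durations must be non-negative")
  }
  if (scenario == "DDM") {
    defaults <- eval(formals(scenario_config)$ddm)
    ddm <- utils::modifyList(defaults, ddm)
    if (ddm$dt <= 0 || ddm$dt > 1 / fs + 1e-12)
      stop("DDM integration step must satisfy 0 < dt <= 1/fs")
    if (ddm$pre_mean < 0 || ddm$post_mean < 0 || ddm$pre_sd < 0 || ddm$post_sd < 0)
      stop("non-decision delay parameters must be non-negative")
  }
  structure(list(scenario = scenario, n_trials = as.integer(n_trials), fs = fs,
                 rt = rt, iti = iti, s_kernel = s_kernel, r_kernel = r_kernel,
                 ramp = ramp, bound = bound, ddm = ddm,
                 sensor_noise_sd = sensor_noise_sd, pad = pad,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s: %d trials @ %g Hz, noise sd %g, seed %d\n",
              x$scenario, x$n_trials, x$fs, x$sensor_noise_sd, x$seed))
  invisible(x)
}

#' Assemble a continuous recording from a scenario config
#'
#' Draws RTs and inter-trial intervals, generates each trial's ground-truth
#' segment, places trials sequentially on the sampling grid and sums the
#' segments into one continuous signal (linear superposition), optionally
#' adding white Gaussian sensor noise. All randomness comes from
#' `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return a list of class `sim_result` with elements `recording`
#'   ([continuous_recording()]), `events` ([event_table()]), `parts` (for SR:
#'   list of the pure-S and pure-R contributions as recordings, otherwise
#'   `NULL`) and `config`.
#' @export
assemble_recording <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- config$n_trials
  segments <- vector("list", n)
  rts <- numeric(n)
  if (config$scenario %in% c("SR", "RAMP")) {
    rts_raw <- draw_rts(n, config$rt)
    rts <- pmax(round(rts_raw * fs), 1) / fs
    if (config$scenario == "RAMP") {
      for (i in seq_len(n))
        segments[[i]] <- make_ramp_trial(rts[i], config$ramp$onset_delay,
                                         config$bound,
                                         config$ramp$post_response_decay, fs)
    }
  } else {
    d <- config$ddm
    for (i in seq_len(n)) {
      pre <- max(0, stats::rnorm(1, d$pre_mean, d$pre_sd))
      post <- max(0, stats::rnorm(1, d$post_mean, d$post_sd))
      tr <- simulate_ddm_trial(d$drift, d$noise_sd, config$bound, d$dt,
                               pre, post, fs, d$post_response_decay,
                               d$max_decision_time, d$max_resample)
      segments[[i]] <- tr$segment
      rts[i] <- tr$rt
    }
  }
  itis <- stats::runif(n, config$iti$min, config$iti$max)
  stim <- numeric(n)
  stim[1] <- round(config$pad * fs) / fs
  if (n > 1) {
    for (i in 2:n)
      stim[i] <- round((stim[i - 1] + rts[i - 1] + itis[i - 1]) * fs) / fs
  }
  resp <- stim + rts
  n_samp <- round((resp[n] + config$pad) * fs) + 1
  # superpose segments; track S/R parts separately for ground-truth bookkeeping
  add_seg <- function(target, i, seg) {
    i0 <- sample_index(stim[i] + seg$offset, fs)
    idx <- i0:(i0 + length(seg$values) - 1)
    if (idx[1] < 1 || idx[length(idx)] > n_samp)
      stop("trial segment falls outside the recording; increase 'pad'")
    target[idx] <- target[idx] + seg$values
    target
  }
  samples <- numeric(n_samp)
  parts <- NULL
  if (config$scenario == "SR") {
    s_sig <- numeric(n_samp)
    r_sig <- numeric(n_samp)
    sk <- config$s_kernel
    rk <- config$r_kernel
    for (i in seq_len(n)) {
      s_sig <- add_seg(s_sig, i, trial_segment(sk$lags[1], sk$values, fs))
      r_sig <- add_seg(r_sig, i, trial_segment(rts[i] + rk$lags[1], rk$values, fs))
    }
    samples <- s_sig + r_sig
    parts <- list(S = continuous_recording(s_sig, fs),
                  R = continuous_recording(r_sig, fs))
  } else {
    for (i in seq_len(n)) samples <- add_seg(samples, i, segments[[i]])
  }
  if (config$sensor_noise_sd > 0)
    samples <- samples + stats::rnorm(n_samp, 0, config$sensor_noise_sd)
  structure(list(recording = continuous_recording(samples, fs),
                 events = event_table(stim, resp),
                 parts = parts, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s scenario: %d trials, %.1f s of signal @ %g Hz\n",
              x$config$scenario, nrow(x$events),
              length(x$recording$samples) / x$recording$fs, x$recording$fs))
  invisible(x)
}
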
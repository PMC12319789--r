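#' Per-trial signal segment
#'
#' A finite stretch of signal on the sampling grid, positioned relative to
#' the trial's stimulus onset.
#'
#' @param offset time of the first sample in seconds relative to stimulus
#'   onset (on the fs grid; may be negative).
#' @param values amplitudes.
#' @param fs sampling rate in Hz.
#' @return an object of class `trial_segment`.
#' @export
trial_segment <- function(offset, values, fs) {
  structure(list(offset = offset, values = as.numeric(values), fs = fs),
            class = "trial_segment")
}

#' @export
print.trial_segment <- function(x, ...) {
  cat(sprintf("<trial_segment> [%g, %g] s re stimulus @ %g Hz\n",
              x$offset, x$offset + (length(x$values) - 1) / x$fs, x$fs))
  invisible(x)
}

#' Ground-truth trial: timescale-invariant S + R components
#'
#' The stimulus kernel is placed at the stimulus and the response kernel at
#' stimulus + RT; where their supports overlap they sum linearly. Neither
#' kernel's amplitude or shape depends on RT (this scenario's defining
#' property).
#'
#' @param rt reaction time in seconds (> one sample).
#' @param s_kernel,r_kernel [waveform_kernel()]s on the `fs` grid.
#' @param fs sampling rate in Hz.
#' @return a [trial_segment()].
#' @export
make_sr_trial <- function(rt, s_kernel, r_kernel, fs) {
  if (s_kernel$fs != fs || r_kernel$fs != fs)
    stop("kernel sampling rates must match 'fs'")
  rt_samp <- round(rt * fs)
  if (rt_samp < 1) stop("'rt' is shorter than one sample")
  s_idx <- round(s_kernel$lags * fs)
  r_idx <- rt_samp + round(r_kernel$lags * fs)
  lo <- min(s_idx[1], r_idx[1])
  hi <- max(s_idx[length(s_idx)], r_idx[length(r_idx)])
  vals <- numeric(hi - lo + 1)
  vals[s_idx - lo + 1] <- vals[s_idx - lo + 1] + s_kernel$values
  vals[r_idx - lo + 1] <- vals[r_idx - lo + 1] + r_kernel$values
  trial_segment(lo / fs, vals, fs)
}

#' Ground-truth trial: stimulus-to-response accumulation ramp
#'
#' Zero until `onset_delay` after the stimulus, then a linear rise reaching
#' `bound(rt)` exactly at the response, then a linear return to zero over
#' `post_response_decay` seconds. The trajectory stretches or contracts with
#' RT, so it is neither stimulus- nor response-locked but interposed between
#' the two. Under a collapsing bound, slower trials terminate lower and rise
#' more shallowly.
#'
#' @param rt reaction time in seconds (> `onset_delay`).
#' @param onset_delay accumulation onset relative to stimulus, seconds.
#' @param bound a `bound_fun` (see [bound_constant()]); must be positive at
#'   `rt`.
#' @param post_response_decay seconds over which the signal returns to zero
#'   after the response (0 = instant).
#' @param fs sampling rate in Hz.
#' @return a [trial_segment()] starting at the stimulus (offset 0).
#' @export
make_ramp_trial <- function(rt, onset_delay, bound, post_response_decay = 0.1, fs) {
  rt_g <- round(rt * fs) / fs
  if (rt_g <= onset_delay) stop("'rt' must exceed 'onset_delay'")
  amp <- bound(rt_g)
  if (amp <= 0) stop("bound must be positive at the response time")
  slope <- amp / (rt_g - onset_delay)
  t <- (0:round((rt_g + post_response_decay) * fs)) / fs
  v <- numeric(length(t))
  ramp <- t >= onset_delay & t <= rt_g
  v[ramp] <- slope * (t[ramp] - onset_delay)
  if (post_response_decay > 0) {
    dec <- t > rt_g
    v[dec] <- pmax(0, amp * (1 - (t[dec] - rt_g) / post_response_decay))
  }
  seg <- trial_segment(0, v, fs)
  attr(seg, "amp_at_response") <- amp
  attr(seg, "slope") <- slope
  seg
}

#' Ground-truth trial: diffusion-type evidence accumulation
#'
#' Euler--Maruyama integration of `dx = drift dt + noise_sd dW` from x = 0
#' until the first crossing of `bound(t)` (single absorbing bound, t counted
#' from accumulation onset). The trajectory is zero during the
#' pre-accumulation delay (stimulus encoding), holds at the crossing value
#' during the post-accumulation (motor) delay, and decays linearly to zero
#' over `post_response_decay` after the response. RT = pre-delay +
#' decision time + post-delay, snapped to the `fs` grid. Non-crossing paths
#' are resampled up to `max_resample` times.
#'
#' @param drift drift rate (evidence units per second, > 0 recommended).
#' @param noise_sd diffusion coefficient (evidence units per sqrt(second)).
#' @param bound a `bound_fun`.
#' @param dt integration step in seconds (<= 1/fs).
#' @param pre_ea_delay,post_ea_delay non-decision delays in seconds (>= 0).
#' @param fs sampling rate of the returned trajectory in Hz.
#' @param post_response_decay post-response linear decay in seconds.
#' @param max_decision_time give up on a path after this many seconds.
#' @param max_resample number of fresh paths to try before erroring.
#' @return list with `segment` (a [trial_segment()], offset 0 = stimulus),
#'   `rt`, `decision_time`, and `crossing_value`.
#' @export
simulate_ddm_trial <- function(drift, noise_sd, bound, dt = 0.001,
                               pre_ea_delay = 0, post_ea_delay = 0, fs = 100,
                               post_response_decay = 0.1,
                               max_decision_time = 10, max_resample = 10) {
  if (dt <= 0) stop("'dt' must be positive")
  if (dt > 1 / fs + 1e-12) stop("'dt' must not exceed the sampling interval 1/fs")
  nmax <- ceiling(max_decision_time / dt)
  run_path <- function() {
    x <- numeric(0)
    x_last <- 0
    done <- 0L
    while (done < nmax) {
      m <- min(4096L, nmax - done)
      inc <- drift * dt + noise_sd * sqrt(dt) * stats::rnorm(m)
      segm <- x_last + cumsum(inc)
      tt <- (done + seq_len(m)) * dt
      hit <- which(segm >= bound(tt))
      x <- c(x, segm)
      if (length(hit)) return(list(k = done + hit[1], x = x))
      x_last <- segm[m]
      done <- done + m
    }
    NULL
  }
  path <- NULL
  for (try in seq_len(max_resample + 1L)) {
    path <- run_path()
    if (!is.null(path)) break
  }
  if (is.null(path))
    stop(sprintf(paste0("diffusion path failed to reach the bound within %g s ",
                        "after %d attempts (drift %g, noise %g); increase drift, ",
                        "lower the bound, or raise 'max_decision_time'"),
                 max_decision_time, max_resample + 1L, drift, noise_sd))
  k <- path$k
  decision_time <- k * dt
  crossing <- path$x[k]
  pre_g <- round(pre_ea_delay / dt) * dt
  rt_raw <- pre_g + decision_time + post_ea_delay
  rt <- max(round(rt_raw * fs), ceiling((pre_g + decision_time) * fs - 1e-9)) / fs
  # trajectory on the fs grid
  t <- (0:round((rt + post_response_decay) * fs)) / fs
  v <- numeric(length(t))
  in_ea <- t >= pre_g & t < pre_g + decision_time
  j <- round((t[in_ea] - pre_g) / dt)
  v[in_ea] <- ifelse(j < 1, 0, path$x[pmax(pmin(j, k), 1L)])
  v[t >= pre_g + decision_time & t <= rt] <- crossing
  if (post_response_decay > 0) {
    dec <- t > rt
    v[dec] <- pmax(0, crossing * (1 - (t[dec] - rt) / post_response_decay))
  }
  list(segment = trial_segment(0, v, fs), rt = rt,
       decision_time = decision_time, crossing_value = crossing)
}
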
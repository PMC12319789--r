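window_cols <- function(es, window) {
  sel <- es$time >= window[1] - 1e-9 & es$time <= window[2] + 1e-9
  if (!any(sel)) stop("measurement window lies outside the epoch")
  sel
}

#' Pre-response amplitude
#'
#' Mean amplitude of each waveform over a short window ending at the
#' response (default the final 50 ms). Applies to response-aligned trial
#' averages or response-locked kernels.
#'
#' @param es an `erp_set` (see [average_by_category()], [kernel_erp_set()]).
#' @param window `c(min, max)` seconds relative to the response.
#' @return named numeric vector, one amplitude per waveform.
#' @export
preresponse_amplitude <- function(es, window = c(-0.05, 0)) {
  sel <- window_cols(es, window)
  vapply(es$waveforms, function(w) mean(w[sel]), numeric(1))
}

#' Buildup slope
#'
#' Slope of the ordinary least-squares line fitted to each waveform over a
#' pre-response window (default -300 to -50 ms), in amplitude units per
#' second.
#'
#' @inheritParams preresponse_amplitude
#' @return named numeric vector of slopes.
#' @export
buildup_slope <- function(es, window = c(-0.30, -0.05)) {
  sel <- window_cols(es, window)
  t <- es$time[sel]
  if (length(t) < 3L) stop("need at least 3 samples in the slope window")
  tc <- t - mean(t)
  vapply(es$waveforms, function(w) sum(tc * (w[sel] - mean(w[sel]))) / sum(tc^2),
         numeric(1))
}

#' Pre-stimulus baseline difference (fast - slow)
#'
#' Difference of window means over the pre-stimulus baseline (default
#' -200 to 0 ms), signed fast minus slow. A nonzero value on
#' stimulus-locked waveforms or S kernels signals component misattribution:
#' activity has been pushed into the period before the stimulus existed.
#'
#' @param es a stimulus-aligned `erp_set` containing `fast` and `slow`
#'   waveforms.
#' @param window `c(min, max)` seconds relative to the stimulus.
#' @return scalar, fast - slow.
#' @export
baseline_difference <- function(es, window = c(-0.2, 0)) {
  if (!all(c("fast", "slow") %in% names(es$waveforms)))
    stop("baseline_difference needs 'fast' and 'slow' waveforms")
  sel <- window_cols(es, window)
  mean(es$waveforms$fast[sel]) - mean(es$waveforms$slow[sel])
}

#' Fast-minus-slow effect
#'
#' All RT "effects" in this package are signed fast - slow; this helper
#' applies that convention to any per-category measurement vector.
#'
#' @param x named numeric vector with elements `fast` and `slow`.
#' @return scalar `x["fast"] - x["slow"]`.
#' @export
rt_effect <- function(x) {
  if (!all(c("fast", "slow") %in% names(x)))
    stop("need named elements 'fast' and 'slow'")
  unname(x["fast"] - x["slow"])
}
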
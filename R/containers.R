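#' Continuous single-channel recording
#'
#' A uniformly sampled amplitude trace, the object that is both simulated and
#' deconvolved. Amplitudes are in arbitrary units; time of the first sample is
#' `t0` seconds.
#'
#' @param samples numeric vector of amplitudes (finite).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds (default 0).
#' @return an object of class `continuous_recording` with elements `samples`,
#'   `fs`, `t0`.
#' @export
continuous_recording <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.continuous_recording <- function(x) length(x$samples)

#' Time axis of a recording
#' @param rec a [continuous_recording()].
#' @return numeric vector of sample times in seconds.
#' @export
rec_time <- function(rec) rec$t0 + (seq_along(rec$samples) - 1) / rec$fs

#' Convert a time in seconds to a 1-based sample index
#'
#' Times are snapped to the nearest sample of the `fs` grid.
#' @param t time(s) in seconds.
#' @param fs sampling rate in Hz.
#' @param t0 time of sample 1 in seconds.
#' @return integer sample indices.
#' @export
sample_index <- function(t, fs, t0 = 0) as.integer(round((t - t0) * fs)) + 1L

#' Per-trial event table
#'
#' The temporal skeleton of a simulation: one row per trial with stimulus
#' onset, response onset, reaction time (RT = response - stimulus) and an RT
#' category assigned by [assign_rt_categories()].
#'
#' @param stim_onset stimulus onsets in seconds from recording start,
#'   non-decreasing.
#' @param resp_onset response onsets in seconds; must exceed `stim_onset`
#'   trial-wise.
#' @param rt_category optional factor/character with levels fast/slow/
#'   unassigned; defaults to all `"unassigned"`.
#' @return a `data.frame` of class `event_table` with columns `trial_id`,
#'   `stim_onset`, `resp_onset`, `rt`, `rt_category`.
#' @export
event_table <- function(stim_onset, resp_onset, rt_category = NULL) {
  n <- length(stim_onset)
  if (length(resp_onset) != n) stop("onset vectors differ in length")
  if (n > 0 && any(resp_onset <= stim_onset))
    stop("every response must follow its stimulus (rt > 0)")
  if (n > 1 && any(diff(stim_onset) < 0))
    stop("stimulus onsets must be non-decreasing")
  if (is.null(rt_category)) rt_category <- rep("unassigned", n)
  rt_category <- factor(as.character(rt_category),
                        levels = c("fast", "slow", "unassigned"))
  if (anyNA(rt_category)) stop("rt_category must be fast, slow or unassigned")
  out <- data.frame(trial_id = seq_len(n),
                    stim_onset = as.numeric(stim_onset),
                    resp_onset = as.numeric(resp_onset),
                    rt = as.numeric(resp_onset - stim_onset),
                    rt_category = rt_category)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Assign fast/slow categories by a median RT split
#'
#' Trials with RT strictly below the median are `fast`, strictly above are
#' `slow`; trials exactly at the median are assigned `fast` (fixed,
#' documented tie rule). Both categories must be non-empty.
#'
#' @param events an [event_table()].
#' @return the event table with `rt_category` filled in.
#' @export
assign_rt_categories <- function(events) {
  if (nrow(events) < 2L) stop("need at least 2 trials for a median split")
  med <- stats::median(events$rt)
  cat <- ifelse(events$rt <= med, "fast", "slow")
  if (!any(cat == "slow"))
    stop("median split degenerate: no trial slower than the median ",
         "(RTs carry no variability)")
  events$rt_category <- factor(cat, levels = c("fast", "slow", "unassigned"))
  events
}
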
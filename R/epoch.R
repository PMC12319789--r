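#' Epoch a continuous recording around events
#'
#' Slices the recording into a trials x time matrix aligned to the stimulus
#' or the response, carrying each trial's RT and category. No baseline
#' correction is applied.
#'
#' @param recording a [continuous_recording()].
#' @param events an [event_table()].
#' @param alignment `"stimulus"` or `"response"`.
#' @param window `c(t_min, t_max)` in seconds relative to the alignment
#'   event; every trial's window must lie inside the recording.
#' @return an object of class `epoch_set`: list with `data` (trials x time),
#'   `time` (lag axis in seconds), `alignment`, `window`, `rt`,
#'   `rt_category`, `fs`.
#' @export
epoch <- function(recording, events, alignment = c("stimulus", "response"),
                  window) {
  alignment <- match.arg(alignment)
  if (nrow(events) == 0L) stop("event table is empty")
  fs <- recording$fs
  w0 <- round(window[1] * fs)
  w1 <- round(window[2] * fs)
  if (w1 <= w0) stop("'window' must be c(min, max) with max > min")
  align_t <- if (alignment == "stimulus") events$stim_onset else events$resp_onset
  a <- sample_index(align_t, fs, recording$t0)
  if (any(a + w0 < 1L) || any(a + w1 > length(recording$samples)))
    stop("epoch window falls outside the recording for at least one trial")
  lag_idx <- w0:w1
  data <- t(vapply(a, function(ai) recording$samples[ai + lag_idx],
                   numeric(length(lag_idx))))
  structure(list(data = data, time = lag_idx / fs, alignment = alignment,
                 window = c(w0, w1) / fs, rt = events$rt,
                 rt_category = events$rt_category, fs = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples, %s-aligned [%g, %g] s\n",
              nrow(x$data), ncol(x$data), x$alignment,
              x$window[1], x$window[2]))
  invisible(x)
}

new_erp_set <- function(time, waveforms, n, alignment, fs) {
  structure(list(time = time, waveforms = waveforms, n = n,
                 alignment = alignment, fs = fs),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("<erp_set> %s-aligned averages [%g, %g] s: %s\n",
              x$alignment, min(x$time), max(x$time),
              paste(sprintf("%s (n=%d)", names(x$waveforms), x$n),
                    collapse = ", ")))
  invisible(x)
}

#' Average epochs within fast/slow RT categories
#'
#' Arithmetic mean across trials within each assigned category.
#'
#' @param epochs an [epoch()] result with categories assigned.
#' @return an `erp_set`: per-category mean waveforms with trial counts.
#' @export
average_by_category <- function(epochs) {
  cats <- c("fast", "slow")
  if (any(epochs$rt_category == "unassigned"))
    stop("RT categories not assigned; run assign_rt_categories() first")
  waves <- list(); n <- integer(0)
  for (cat in cats) {
    sel <- epochs$rt_category == cat
    if (!any(sel)) stop("RT category '", cat, "' is empty")
    waves[[cat]] <- colMeans(epochs$data[sel, , drop = FALSE])
    n[cat] <- sum(sel)
  }
  new_erp_set(epochs$time, waves, n, epochs$alignment, epochs$fs)
}

#' Average all epochs into a single waveform
#'
#' @param epochs an [epoch()] result.
#' @return an `erp_set` with one waveform `"all"`.
#' @export
average_epochs <- function(epochs) {
  new_erp_set(epochs$time, list(all = colMeans(epochs$data)),
              c(all = nrow(epochs$data)), epochs$alignment, epochs$fs)
}

#' Fitted kernels as an erp_set
#'
#' Re-expresses the by-category kernels of one event type as event-locked
#' waveforms, so the same amplitude/slope/baseline measurements apply to
#' estimated kernels as to trial averages.
#'
#' @param fit an `rerp_fit` whose chosen event type used the
#'   `by_rt_category` scheme (or pooled, giving one waveform).
#' @param event `"S"` or `"R"`.
#' @return an `erp_set` over the event's lag window.
#' @export
kernel_erp_set <- function(fit, event = c("S", "R")) {
  event <- match.arg(event)
  cm <- fit$colmap[fit$colmap$event == event, ]
  if (nrow(cm) == 0L) stop("no '", event, "' predictors in this fit")
  waves <- list(); n <- integer(0)
  for (p in unique(cm$predictor)) {
    sub <- cm[cm$predictor == p, ]
    o <- order(sub$lag_s)
    nm <- if (identical(unique(sub$category), "pooled")) "pooled"
          else unique(sub$category)
    waves[[nm]] <- fit$coefficients[sub$col[o]]
    n[nm] <- sum(fit$events$rt_category == nm)
  }
  lags <- sort(unique(cm$lag_s))
  new_erp_set(lags, waves, n,
              if (event == "S") "stimulus" else "response", fit$fs)
}
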
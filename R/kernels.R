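#' Waveform kernel on the sampling grid
#'
#' A lag-indexed waveform locked to an event (stimulus or response). Lags are
#' seconds relative to the locking event and must sit on the `fs` grid.
#'
#' @param lags numeric vector of lags in seconds, uniformly spaced at `1/fs`.
#' @param values amplitudes, same length as `lags`.
#' @param fs sampling rate in Hz.
#' @return an object of class `waveform_kernel`.
#' @export
waveform_kernel <- function(lags, values, fs) {
  if (length(lags) != length(values)) stop("lags/values length mismatch")
  if (length(lags) > 1L) {
    step <- diff(lags)
    if (any(abs(step - 1 / fs) > 1e-9))
      stop("kernel lag grid must match 1/fs exactly")
  }
  if (any(abs(round(lags * fs) - lags * fs) > 1e-6))
    stop("kernel lags must lie on the fs sampling grid")
  structure(list(lags = as.numeric(lags), values = as.numeric(values), fs = fs),
            class = "waveform_kernel")
}

#' @export
print.waveform_kernel <- function(x, ...) {
  cat(sprintf("<waveform_kernel> support [%g, %g] s @ %g Hz, peak %g\n",
              min(x$lags), max(x$lags), x$fs, max(abs(x$values))))
  invisible(x)
}

#' Smooth unimodal Hanning-profile kernel
#'
#' A raised-cosine bump of given total width, centred on `peak_time`. Used as
#' the default shape for the timescale-invariant stimulus and response
#' components: smooth, compactly supported, RT-independent.
#'
#' @param peak_time lag of the peak in seconds (relative to locking event).
#' @param width total support width in seconds.
#' @param amplitude peak amplitude.
#' @param fs sampling rate in Hz.
#' @return a [waveform_kernel()].
#' @export
hanning_kernel <- function(peak_time, width, amplitude = 1, fs) {
  if (width <= 0) stop("'width' must be positive")
  half <- width / 2
  # snap support ends to the grid
  l0 <- round((peak_time - half) * fs) / fs
  l1 <- round((peak_time + half) * fs) / fs
  lags <- seq(l0, l1, by = 1 / fs)
  phase <- (lags - peak_time) / half            # in [-1, 1]
  vals <- amplitude * 0.5 * (1 + cos(pi * pmin(pmax(phase, -1), 1)))
  waveform_kernel(lags, vals, fs)
}

#' Decision bound functions
#'
#' A bound maps within-trial time (seconds from accumulation onset) to a
#' positive threshold. `bound_constant` is flat; `bound_collapsing` decays
#' exponentially from `b0` towards a positive asymptote `b_asym` with time
#' constant `tau`, so later responses terminate at lower accumulator values.
#'
#' @param b0 bound at t = 0 (amplitude units, > 0).
#' @param b_asym asymptotic bound (> 0, < `b0`).
#' @param tau collapse time constant in seconds (> 0).
#' @return a function `f(t)` of class `bound_fun`, carrying its kind and
#'   parameters as attributes (so it can be serialized and rebuilt).
#' @export
bound_constant <- function(b0) {
  if (b0 <= 0) stop("'b0' must be positive")
  f <- function(t) rep_len(b0, length(t))
  structure(f, class = c("bound_fun", "function"),
            kind = "constant", params = list(b0 = b0))
}

#' @rdname bound_constant
#' @export
bound_collapsing <- function(b0, b_asym = 0.4 * b0, tau = 1) {
  if (b0 <= 0 || b_asym <= 0 || tau <= 0) stop("bound parameters must be positive")
  if (b_asym >= b0) stop("'b_asym' must be below 'b0' for a collapsing bound")
  f <- function(t) b_asym + (b0 - b_asym) * exp(-t / tau)
  structure(f, class = c("bound_fun", "function"),
            kind = "collapsing", params = list(b0 = b0, b_asym = b_asym, tau = tau))
}

#' Rebuild a bound function from its serialized parameters
#' @param kind `"constant"` or `"collapsing"`.
#' @param params named list of parameters as stored on a `bound_fun`.
#' @return a `bound_fun`.
#' @export
bound_from_params <- function(kind, params) {
  switch(kind,
         constant = bound_constant(params$b0),
         collapsing = bound_collapsing(params$b0, params$b_asym, params$tau),
         stop("unknown bound kind: ", kind))
}

#' @export
print.bound_fun <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<bound_fun> %s: %s\n", attr(x, "kind"),
              paste(names(p), unlist(p), sep = " = ", collapse = ", ")))
  invisible(x)
}
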
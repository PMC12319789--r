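#' Specification of a time-expanded (FIR) deconvolution design
#'
#' For each event type (stimulus `S`, response `R`) a lag window over which
#' that event's kernel is estimated, and a predictor scheme: `"pooled"` (one
#' kernel per event type) or `"by_rt_category"` (one kernel per event type x
#' fast/slow category, coded as separate indicator columns so each
#' category's kernel is directly the estimated waveform).
#'
#' @param fs sampling rate in Hz.
#' @param s_window,r_window lag windows `c(min, max)` in seconds relative to
#'   the stimulus / response event.
#' @param s_scheme,r_scheme `"pooled"` or `"by_rt_category"`.
#' @param intercept add a constant column (default `FALSE`; simulated data
#'   are zero-mean between trials).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(fs, s_window = c(-0.2, 1.0), r_window = c(-0.8, 0.2),
                        s_scheme = c("pooled", "by_rt_category"),
                        r_scheme = c("pooled", "by_rt_category"),
                        intercept = FALSE) {
  s_scheme <- match.arg(s_scheme)
  r_scheme <- match.arg(r_scheme)
  chk <- function(w, nm) {
    if (length(w) != 2L || w[2] <= w[1])
      stop("'", nm, "' must be c(min, max) with max > min")
    round(w * fs) / fs
  }
  structure(list(fs = fs, s_window = chk(s_window, "s_window"),
                 r_window = chk(r_window, "r_window"),
                 s_scheme = s_scheme, r_scheme = r_scheme,
                 intercept = intercept),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> S: [%g, %g] s (%s); R: [%g, %g] s (%s)%s\n",
              x$s_window[1], x$s_window[2], x$s_scheme,
              x$r_window[1], x$r_window[2], x$r_scheme,
              if (x$intercept) "; +intercept" else ""))
  invisible(x)
}

predictor_plan <- function(events, spec) {
  plan <- list()
  add <- function(plan, event, scheme, window) {
    lag0 <- round(window[1] * spec$fs)
    lag1 <- round(window[2] * spec$fs)
    onsets <- if (event == "S") events$stim_onset else events$resp_onset
    if (scheme == "pooled") {
      plan[[length(plan) + 1L]] <- list(name = event, event = event,
                                        category = "pooled",
                                        lags = lag0:lag1, onsets = onsets)
    } else {
      if (any(events$rt_category == "unassigned"))
        stop("by_rt_category scheme requires assigned RT categories; ",
             "run assign_rt_categories() first")
      for (cat in c("fast", "slow")) {
        sel <- events$rt_category == cat
        if (!any(sel)) stop("RT category '", cat, "' is empty")
        plan[[length(plan) + 1L]] <- list(name = paste(event, cat, sep = "_"),
                                          event = event, category = cat,
                                          lags = lag0:lag1,
                                          onsets = onsets[sel])
      }
    }
    plan
  }
  plan <- add(plan, "S", spec$s_scheme, spec$s_window)
  plan <- add(plan, "R", spec$r_scheme, spec$r_window)
  plan
}

#' Build a sparse time-expanded design matrix
#'
#' Rows are recording samples; columns are (predictor, lag) pairs. Column
#' (p, l) is a 0/1 indicator: sample s carries a 1 iff an event of predictor
#' p occurred at sample s - l. Every event's full lag window must fall
#' inside the recording.
#'
#' @param events an [event_table()] (categories assigned if a
#'   `by_rt_category` scheme is used).
#' @param spec a [design_spec()].
#' @param n_samples number of rows (samples in the recording).
#' @param t0 time of sample 1 in seconds.
#' @return an object of class `time_expanded_design`: list with the sparse
#'   matrix `X`, a `colmap` data.frame (`col`, `predictor`, `event`,
#'   `category`, `lag_s`), the `spec` and `n_samples`.
#' @export
build_design <- function(events, spec, n_samples, t0 = 0) {
  if (nrow(events) == 0L) stop("event table is empty")
  plan <- predictor_plan(events, spec)
  ri <- list(); ci <- list()
  colmap <- list()
  col_off <- 0L
  for (p in plan) {
    ev_samp <- sample_index(p$onsets, spec$fs, t0)
    nl <- length(p$lags)
    rows <- rep(ev_samp, each = nl) + rep(p$lags, times = length(ev_samp))
    if (any(rows < 1L) || any(rows > n_samples))
      stop("time-expansion window for predictor '", p$name,
           "' falls outside the recording")
    ri[[length(ri) + 1L]] <- rows
    ci[[length(ci) + 1L]] <- rep(col_off + seq_len(nl), times = length(ev_samp))
    colmap[[length(colmap) + 1L]] <-
      data.frame(col = col_off + seq_len(nl), predictor = p$name,
                 event = p$event, category = p$category,
                 lag_s = p$lags / spec$fs)
    col_off <- col_off + nl
  }
  if (spec$intercept) {
    ri[[length(ri) + 1L]] <- seq_len(n_samples)
    ci[[length(ci) + 1L]] <- rep(col_off + 1L, n_samples)
    colmap[[length(colmap) + 1L]] <-
      data.frame(col = col_off + 1L, predictor = "intercept",
                 event = "intercept", category = "pooled", lag_s = NA_real_)
    col_off <- col_off + 1L
  }
  X <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = 1,
                            dims = c(n_samples, col_off))
  structure(list(X = X, colmap = do.call(rbind, colmap), spec = spec,
                 n_samples = n_samples, t0 = t0),
            class = "time_expanded_design")
}

#' @export
print.time_expanded_design <- function(x, ...) {
  cat(sprintf("<time_expanded_design> %d samples x %d (predictor, lag) columns [%s]\n",
              x$n_samples, ncol(x$X),
              paste(unique(x$colmap$predictor), collapse = ", ")))
  invisible(x)
}
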
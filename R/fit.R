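#' Fit an overlap-corrected deconvolution model
#'
#' Estimates stimulus- and response-locked FIR kernels jointly by least
#' squares over the whole continuous recording: all predictors are fit
#' simultaneously, so overlapping event responses are disentangled rather
#' than averaged together. The sparse normal equations are solved by a
#' direct sparse Cholesky factorization (no regularization); on these 0/1
#' stick designs the solution matches a dense least-squares oracle to
#' numerical precision.
#'
#' @param recording a [continuous_recording()].
#' @param events an [event_table()]; categories must be assigned when the
#'   spec uses a `by_rt_category` scheme.
#' @param spec a [design_spec()]; defaults to pooled S `[-0.2, 1.0]` s and
#'   pooled R `[-0.8, 0.2]` s windows at the recording's sampling rate.
#' @param design optionally a pre-built [build_design()] result (must match
#'   `recording`); when supplied, `events`/`spec` are taken from it.
#' @return an object of class `rerp_fit`: the fitted kernels (`coefficients`
#'   plus `colmap`), the design, per-fit diagnostics (`sigma2` residual
#'   variance, `r_squared` fraction of variance explained), and the data
#'   needed by the methods.
#' @seealso [coef.rerp_fit()], [predict.rerp_fit()], [residual_fraction()]
#' @export
deconv_fit <- function(recording, events, spec = NULL, design = NULL) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (is.null(design)) {
    if (is.null(spec)) spec <- design_spec(fs = recording$fs)
    if (abs(spec$fs - recording$fs) > 1e-9)
      stop("design spec fs must match the recording fs")
    design <- build_design(events, spec, length(recording$samples), recording$t0)
  }
  X <- design$X
  y <- recording$samples
  if (nrow(X) != length(y)) stop("design and recording differ in length")
  XtX <- Matrix::crossprod(X)
  Xty <- as.numeric(Matrix::crossprod(X, y))
  beta <- tryCatch(
    as.numeric(Matrix::solve(XtX, Xty)),
    error = function(e) {
      stop("design is rank deficient: stimulus- and response-lag columns are ",
           "collinear (typically insufficient RT jitter between S and R ",
           "events, or an empty predictor). Underlying error: ",
           conditionMessage(e), call. = FALSE)
    })
  # guard against a numerically meaningless solve (near-singular Gram matrix)
  nr <- sqrt(sum((as.numeric(XtX %*% beta) - Xty)^2)) / max(sqrt(sum(Xty^2)), 1e-12)
  if (!is.finite(nr) || nr > 1e-6)
    stop("normal equations solved to relative residual ", signif(nr, 3),
         ": design is numerically rank deficient (insufficient RT jitter?)")
  fitted <- as.numeric(X %*% beta)
  res <- y - fitted
  structure(list(coefficients = beta, colmap = design$colmap,
                 design = design, events = events, spec = design$spec,
                 fs = recording$fs, t0 = recording$t0,
                 y = y, fitted_values = fitted,
                 sigma2 = stats::var(res),
                 r_squared = if (stats::var(y) > 0) 1 - stats::var(res) / stats::var(y) else NA_real_,
                 call = match.call()),
            class = "rerp_fit")
}

#' Extract fitted kernels
#'
#' @param object an `rerp_fit`.
#' @param format `"kernels"` for a named list of [waveform_kernel()]s (one
#'   per predictor), `"long"` for a tidy data.frame (`predictor`, `event`,
#'   `category`, `lag_s`, `beta`).
#' @param ... unused.
#' @return kernels or a data.frame, per `format`.
#' @export
coef.rerp_fit <- function(object, format = c("kernels", "long"), ...) {
  format <- match.arg(format)
  cm <- object$colmap
  if (format == "long") {
    out <- cm
    out$beta <- object$coefficients[cm$col]
    return(out[, c("predictor", "event", "category", "lag_s", "beta")])
  }
  preds <- unique(cm$predictor)
  preds <- setdiff(preds, "intercept")
  kernels <- lapply(preds, function(p) {
    sel <- cm$predictor == p
    waveform_kernel(cm$lag_s[sel], object$coefficients[cm$col[sel]], object$fs)
  })
  names(kernels) <- preds
  kernels
}

#' Predict the modeled contribution of selected predictors
#'
#' Reconstructs, as a continuous signal, the part of the fit carried by a
#' subset of predictors (design columns of the subset times their betas).
#' With all predictors selected, prediction + residuals reproduce the
#' recording exactly.
#'
#' @param object an `rerp_fit`.
#' @param which predictors to include: names from `object$colmap$predictor`
#'   (e.g. `"S"`, `"R_fast"`), or an event type (`"S"`/`"R"`) which selects
#'   all its categories; `NULL` (default) selects everything;
#'   `character(0)` gives an all-zero signal.
#' @param ... unused.
#' @return a [continuous_recording()] of the selected contribution.
#' @export
predict.rerp_fit <- function(object, which = NULL, ...) {
  cm <- object$colmap
  if (is.null(which)) {
    sel <- rep(TRUE, nrow(cm))
  } else {
    known <- unique(c(cm$predictor, cm$event))
    bad <- setdiff(which, known)
    if (length(bad))
      stop("unknown predictor(s): ", paste(bad, collapse = ", "),
           " (available: ", paste(unique(cm$predictor), collapse = ", "), ")")
    sel <- cm$predictor %in% which | cm$event %in% which
  }
  if (!any(sel))
    return(continuous_recording(numeric(length(object$y)), object$fs, object$t0))
  cols <- cm$col[sel]
  sig <- as.numeric(object$design$X[, cols, drop = FALSE] %*%
                      object$coefficients[cols])
  continuous_recording(sig, object$fs, object$t0)
}

#' @export
fitted.rerp_fit <- function(object, ...) object$fitted_values

#' @export
residuals.rerp_fit <- function(object, ...) object$y - object$fitted_values

#' @export
print.rerp_fit <- function(x, ...) {
  preds <- unique(x$colmap$predictor)
  cat("Overlap-corrected deconvolution fit (FIR least squares)\n")
  cat(sprintf("  %d samples @ %g Hz; %d trials; %d predictors (%s); %d betas\n",
              length(x$y), x$fs, nrow(x$events), length(preds),
              paste(preds, collapse = ", "), length(x$coefficients)))
  cat(sprintf("  variance explained: %.4f; residual variance: %.3g\n",
              x$r_squared, x$sigma2))
  invisible(x)
}

#' @export
summary.rerp_fit <- function(object, ...) {
  ker <- coef(object)
  peaks <- vapply(ker, function(k) k$values[which.max(abs(k$values))], numeric(1))
  out <- list(predictors = names(ker), peaks = peaks,
              r_squared = object$r_squared, sigma2 = object$sigma2,
              residual_fraction = 1 - object$r_squared,
              n_trials = nrow(object$events),
              n_betas = length(object$coefficients),
              spec = object$spec)
  class(out) <- "summary.rerp_fit"
  out
}

#' @export
print.summary.rerp_fit <- function(x, ...) {
  cat("Deconvolution fit summary\n")
  print(x$spec)
  cat(sprintf("  trials: %d; betas: %d\n", x$n_trials, x$n_betas))
  cat(sprintf("  fraction of variance explained: %.4f (residual fraction %.4f)\n",
              x$r_squared, x$residual_fraction))
  cat("  kernel peaks (signed, at max |beta|):\n")
  for (p in names(x$peaks)) cat(sprintf("    %-8s %8.4f\n", p, x$peaks[[p]]))
  invisible(x)
}

#' Plot fitted kernels
#'
#' One panel per event type, one line per predictor, lag on the x axis.
#'
#' @param x an `rerp_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rerp_fit <- function(x, ...) {
  cm <- x$colmap
  evs <- setdiff(unique(cm$event), "intercept")
  old <- graphics::par(mfrow = c(1, length(evs)))
  on.exit(graphics::par(old))
  for (ev in evs) {
    sub <- cm[cm$event == ev, ]
    preds <- unique(sub$predictor)
    lags <- sort(unique(sub$lag_s))
    mat <- sapply(preds, function(p) {
      s <- sub[sub$predictor == p, ]
      x$coefficients[s$col[order(s$lag_s)]]
    })
    graphics::matplot(lags, mat, type = "l", lty = 1,
                      col = seq_along(preds),
                      xlab = sprintf("lag re %s (s)",
                                     if (ev == "S") "stimulus" else "response"),
                      ylab = "beta (a.u.)", main = paste(ev, "kernels"), ...)
    graphics::abline(v = 0, lty = 3)
    graphics::legend("topright", legend = preds, col = seq_along(preds),
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate recordings from a fitted deconvolution model
#'
#' Generates new continuous recordings as the fitted event-locked prediction
#' plus white Gaussian noise at the fit's residual standard deviation (the
#' model's own account of the data).
#'
#' @param object an `rerp_fit`.
#' @param nsim number of recordings.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of [continuous_recording()]s.
#' @export
simulate.rerp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(max(object$sigma2, 0))
  lapply(seq_len(nsim), function(i)
    continuous_recording(object$fitted_values +
                           stats::rnorm(length(object$y), 0, sd),
                         object$fs, object$t0))
}

#' Subtract a modeled component from a recording
#'
#' Pointwise difference, e.g. removing the estimated S component before
#' response-locked re-averaging ("overlap correction" as practised).
#'
#' @param recording,component [continuous_recording()]s of equal length,
#'   sampling rate and start time.
#' @return a [continuous_recording()].
#' @export
subtract_component <- function(recording, component) {
  stopifnot(inherits(recording, "continuous_recording"),
            inherits(component, "continuous_recording"))
  if (length(recording$samples) != length(component$samples) ||
      abs(recording$fs - component$fs) > 1e-9)
    stop("recording and component differ in length or sampling rate")
  continuous_recording(recording$samples - component$samples,
                       recording$fs, recording$t0)
}

#' Fraction of recording variance left unexplained by a fit
#'
#' @param recording the [continuous_recording()] that was fit.
#' @param fit an `rerp_fit` on that recording.
#' @return residual variance divided by recording variance, in `[0, 1]` up
#'   to sampling noise.
#' @export
residual_fraction <- function(recording, fit) {
  v <- stats::var(recording$samples)
  if (v <= 0) stop("recording has zero variance")
  stats::var(recording$samples - fit$fitted_values) / v
}
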
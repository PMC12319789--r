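default_windows <- list(stim = c(-0.3, 1.2), resp = c(-1.0, 0.3),
                        amp = c(-0.05, 0), slope = c(-0.30, -0.05),
                        baseline = c(-0.2, 0))

measure_response_locked <- function(es, windows) {
  amp <- preresponse_amplitude(es, windows$amp)
  slope <- buildup_slope(es, windows$slope)
  list(amplitude = amp, slope = slope,
       amp_effect = rt_effect(amp), slope_effect = rt_effect(slope),
       windows = windows[c("amp", "slope")])
}

new_panel_report <- function(panel, config, ...) {
  structure(c(list(panel = panel, scenario = config$scenario,
                   config = config), list(...)),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("<panel_report %s> scenario %s (%d trials, seed %d)\n",
              x$panel, x$scenario, x$config$n_trials, x$config$seed))
  if (!is.null(x$uncorrected))
    cat(sprintf("  uncorrected fast-slow: amplitude %+.4f, slope %+.4f\n",
                x$uncorrected$amp_effect, x$uncorrected$slope_effect))
  if (!is.null(x$corrected))
    cat(sprintf("  S-subtracted fast-slow: amplitude %+.4f, slope %+.4f\n",
                x$corrected$amp_effect, x$corrected$slope_effect))
  if (!is.null(x$attenuation))
    cat(sprintf("  attenuation |corrected/uncorrected|: amplitude %.3f, slope %.3f\n",
                x$attenuation["amplitude"], x$attenuation["slope"]))
  if (!is.null(x$s_kernel_baseline_difference))
    cat(sprintf("  S-kernel baseline difference (fast-slow): %+.5f\n",
                x$s_kernel_baseline_difference))
  if (!is.null(x$residual_fraction))
    cat(sprintf("  residual fraction after removing S and R: %.4f\n",
                x$residual_fraction))
  invisible(x)
}

#' Uncorrected trial averages (panels a/b)
#'
#' Simulates one scenario, splits trials at the median RT, and reports the
#' uncorrected stimulus- and response-locked fast/slow averages with
#' pre-response amplitude, buildup slope and baseline measurements. For the
#' SR world this exhibits the spurious overlap-induced RT effect; for the
#' RAMP/DDM worlds the RT effects are real features of the ground truth.
#'
#' @param config a [scenario_config()].
#' @param windows list overriding the default epoch/measurement windows
#'   (`stim`, `resp`, `amp`, `slope`, `baseline`).
#' @return a `panel_report`.
#' @export
run_panel_ab <- function(config, windows = list()) {
  windows <- utils::modifyList(default_windows, windows)
  sim <- assemble_recording(config)
  events <- assign_rt_categories(sim$events)
  ep_s <- epoch(sim$recording, events, "stimulus", windows$stim)
  ep_r <- epoch(sim$recording, events, "response", windows$resp)
  avg_s <- average_by_category(ep_s)
  avg_r <- average_by_category(ep_r)
  new_panel_report(if (config$scenario == "SR") "a" else "b", config,
                   events = events,
                   stim_locked = avg_s, resp_locked = avg_r,
                   uncorrected = measure_response_locked(avg_r, windows),
                   baseline_difference = baseline_difference(avg_s, windows$baseline),
                   windows = windows)
}

#' S-subtraction correction (panels c/d)
#'
#' Fits the deconvolution model with a pooled S kernel and by-RT-category R
#' kernels (all jointly), subtracts the estimated S component from the
#' recording, and compares response-locked fast/slow effects before and
#' after. Reports attenuation ratios |corrected| / |uncorrected| and the S
#' component's share of the event-locked predicted variance.
#'
#' @inheritParams run_panel_ab
#' @return a `panel_report` with elements `fit`, `uncorrected`, `corrected`,
#'   `attenuation`, `s_variance_share`.
#' @export
run_panel_cd <- function(config, windows = list()) {
  windows <- utils::modifyList(default_windows, windows)
  sim <- assemble_recording(config)
  events <- assign_rt_categories(sim$events)
  spec <- design_spec(fs = config$fs, s_scheme = "pooled",
                      r_scheme = "by_rt_category")
  fit <- deconv_fit(sim$recording, events, spec)
  s_pred <- predict(fit, "S")
  corrected_rec <- subtract_component(sim$recording, s_pred)
  avg_un <- average_by_category(epoch(sim$recording, events, "response", windows$resp))
  avg_co <- average_by_category(epoch(corrected_rec, events, "response", windows$resp))
  un <- measure_response_locked(avg_un, windows)
  co <- measure_response_locked(avg_co, windows)
  att <- c(amplitude = abs(co$amp_effect) / abs(un$amp_effect),
           slope = abs(co$slope_effect) / abs(un$slope_effect))
  full_pred <- predict(fit)
  share <- stats::var(s_pred$samples) / stats::var(full_pred$samples)
  new_panel_report(if (config$scenario == "SR") "c" else "d", config,
                   events = events, fit = fit,
                   resp_locked_uncorrected = avg_un, resp_locked_corrected = avg_co,
                   uncorrected = un, corrected = co, attenuation = att,
                   s_variance_share = share, windows = windows)
}

#' RT effects in both components and residual activity (panels e/f)
#'
#' Fits by-RT-category S and R kernels jointly and measures the fast-slow
#' difference of the estimated S kernels in the pre-stimulus baseline. Also
#' fits the RT-agnostic pooled S + R model and reports the fraction of
#' recording variance left after removing both components.
#'
#' @inheritParams run_panel_ab
#' @return a `panel_report` with elements `fit_bycat`, `fit_pooled`,
#'   `s_kernels`, `s_kernel_baseline_difference`, `residual_fraction`.
#' @export
run_panel_ef <- function(config, windows = list()) {
  windows <- utils::modifyList(default_windows, windows)
  sim <- assemble_recording(config)
  events <- assign_rt_categories(sim$events)
  spec_bc <- design_spec(fs = config$fs, s_scheme = "by_rt_category",
                         r_scheme = "by_rt_category")
  fit_bc <- deconv_fit(sim$recording, events, spec_bc)
  s_ker <- kernel_erp_set(fit_bc, "S")
  bdiff <- baseline_difference(s_ker, windows$baseline)
  spec_pool <- design_spec(fs = config$fs)
  fit_pool <- deconv_fit(sim$recording, events, spec_pool)
  rf <- residual_fraction(sim$recording, fit_pool)
  new_panel_report(if (config$scenario == "SR") "e" else "f", config,
                   events = events, fit_bycat = fit_bc, fit_pooled = fit_pool,
                   s_kernels = s_ker,
                   s_kernel_baseline_difference = bdiff,
                   s_kernel_peaks = vapply(s_ker$waveforms, max, numeric(1)),
                   residual_fraction = rf, windows = windows)
}

#' Non-decision-jitter attribution experiment
#'
#' For a diffusion-type scenario, varies the ratio of post-accumulation
#' (motor) to pre-accumulation (encoding) non-decision delay jitter while
#' holding the total delay mean and total jitter SD fixed. For each ratio it
#' fits the pooled S + R model and reports the S component's share of the
#' event-locked predicted variance, and fits the by-category model to
#' report the fast/slow S-kernel peaks. The more jitter sits after
#' accumulation, the less response-locked the EA signal is, and the more of
#' it the regression attributes to the S component.
#'
#' @param config a DDM [scenario_config()].
#' @param ratios post/pre jitter SD ratios to test (>= 3 values).
#' @param nd_sd_total total non-decision jitter SD in seconds, split between
#'   pre and post delays as `pre_sd = nd_sd_total / sqrt(1 + r^2)`,
#'   `post_sd = r * pre_sd`.
#' @param windows see [run_panel_ab()].
#' @return an object of class `jitter_report`: a summary `data.frame`
#'   (`ratio`, `pre_sd`, `post_sd`, `s_variance_share`, `s_peak_fast`,
#'   `s_peak_slow`, `s_peak_effect`) plus the per-ratio fits.
#' @export
run_jitter_experiment <- function(config, ratios = c(0, 0.5, 1, 2, 4),
                                  nd_sd_total = 0.05, windows = list()) {
  if (config$scenario != "DDM")
    stop("the jitter experiment requires a DDM scenario config")
  if (length(ratios) < 3L) stop("need at least 3 jitter ratios")
  windows <- utils::modifyList(default_windows, windows)
  rows <- vector("list", length(ratios))
  details <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    cfg <- config
    cfg$ddm$pre_sd <- nd_sd_total / sqrt(1 + r^2)
    cfg$ddm$post_sd <- r * cfg$ddm$pre_sd
    sim <- assemble_recording(cfg)
    events <- assign_rt_categories(sim$events)
    fit_pool <- deconv_fit(sim$recording, events, design_spec(fs = cfg$fs))
    s_pred <- predict(fit_pool, "S")
    full_pred <- predict(fit_pool)
    share <- stats::var(s_pred$samples) / stats::var(full_pred$samples)
    fit_bc <- deconv_fit(sim$recording, events,
                         design_spec(fs = cfg$fs, s_scheme = "by_rt_category",
                                     r_scheme = "by_rt_category"))
    s_ker <- kernel_erp_set(fit_bc, "S")
    pk <- vapply(s_ker$waveforms, max, numeric(1))
    rows[[i]] <- data.frame(ratio = r, pre_sd = cfg$ddm$pre_sd,
                            post_sd = cfg$ddm$post_sd,
                            s_variance_share = share,
                            s_peak_fast = pk[["fast"]],
                            s_peak_slow = pk[["slow"]],
                            s_peak_effect = pk[["fast"]] - pk[["slow"]])
    details[[i]] <- list(fit_pooled = fit_pool, fit_bycat = fit_bc,
                         events = events)
  }
  structure(list(summary = do.call(rbind, rows), details = details,
                 config = config, nd_sd_total = nd_sd_total),
            class = "jitter_report")
}

#' @export
print.jitter_report <- function(x, ...) {
  cat("<jitter_report> S attribution vs post/pre non-decision jitter ratio\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full analysis ladder
#'
#' Runs panels a--f (uncorrected averages, S-subtraction, both-components +
#' residual analyses, each on the SR and RAMP worlds) and the non-decision
#' jitter experiment on the DDM world, with seeds derived from one master
#' seed. Re-running with the same seed is bit-identical.
#'
#' @param seed master integer seed.
#' @param n_trials trials per scenario.
#' @param out_dir optional directory; when given, per-panel waveforms (TSV)
#'   and a JSON summary are written there along with the resolved configs.
#' @return list of class `rerpsim_run`: panel reports `a`..`f`, `jitter`,
#'   and a `summary` data.frame of the headline effects.
#' @export
run_all <- function(seed = 1, n_trials = 500, out_dir = NULL) {
  cfg_sr <- scenario_config("SR", n_trials = n_trials, seed = seed)
  cfg_rp <- scenario_config("RAMP", n_trials = n_trials, seed = seed + 1)
  cfg_dd <- scenario_config("DDM", n_trials = n_trials, seed = seed + 2)
  reports <- list(a = run_panel_ab(cfg_sr), b = run_panel_ab(cfg_rp),
                  c = run_panel_cd(cfg_sr), d = run_panel_cd(cfg_rp),
                  e = run_panel_ef(cfg_sr), f = run_panel_ef(cfg_rp),
                  jitter = run_jitter_experiment(cfg_dd))
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  srow <- function(p) data.frame(
    panel = p$panel, scenario = p$scenario,
    amp_effect_uncorrected = num(p$uncorrected$amp_effect),
    slope_effect_uncorrected = num(p$uncorrected$slope_effect),
    amp_effect_corrected = num(p$corrected$amp_effect),
    slope_effect_corrected = num(p$corrected$slope_effect),
    s_kernel_baseline_difference = num(p$s_kernel_baseline_difference),
    residual_fraction = num(p$residual_fraction))
  summary <- do.call(rbind, lapply(reports[c("a", "b", "c", "d", "e", "f")], srow))
  out <- structure(c(reports, list(summary = summary, seed = seed)),
                   class = "rerpsim_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.rerpsim_run <- function(x, ...) {
  cat(sprintf("<rerpsim_run> seed %d\n", x$seed))
  print(x$summary, row.names = FALSE, digits = 4)
  cat("jitter experiment:\n")
  print(x$jitter$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
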
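#' Read/write event tables as BIDS-style events.tsv
#'
#' One row per trial: `onset` (stimulus onset, s), `duration` (0),
#' `trial_type`, `response_time` (RT, s), plus the package's `rt_category`.
#'
#' @param events an [event_table()].
#' @param path file path (tab-separated).
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   [event_table()].
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset = events$stim_onset, duration = 0,
                    trial_type = "trial",
                    response_time = events$rt,
                    rt_category = as.character(events$rt_category))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  event_table(d$onset, d$onset + d$response_time,
              rt_category = if ("rt_category" %in% names(d)) d$rt_category else NULL)
}

#' Read/write a continuous recording as TSV
#'
#' Plain-text serialization: a `# fs=<Hz> t0=<s>` header line followed by
#' one amplitude per row.
#'
#' @param rec a [continuous_recording()].
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording` a
#'   [continuous_recording()].
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g t0=%.10g", rec$fs, rec$t0), con)
  writeLines(sprintf("%.17g", rec$samples), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("# fs=([0-9.eE+-]+) t0=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3L) stop("not a recording file (missing '# fs=... t0=...' header)")
  vals <- utils::read.table(path, skip = 1L)[[1]]
  continuous_recording(vals, as.numeric(m[2]), as.numeric(m[3]))
}

#' Write fitted kernels as tidy long-format TSV
#'
#' Columns: `predictor`, `event`, `category`, `lag_s`, `beta`.
#'
#' @param fit an `rerp_fit`.
#' @param path file path.
#' @export
write_kernels <- function(fit, path) {
  utils::write.table(coef(fit, "long"), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-category average waveforms as tidy TSV
#'
#' Columns: `category`, `time_s`, `amplitude`, `n_trials`.
#'
#' @param es an `erp_set`.
#' @param path file path.
#' @export
write_erp_set <- function(es, path) {
  rows <- lapply(names(es$waveforms), function(cat)
    data.frame(category = cat, time_s = es$time,
               amplitude = es$waveforms[[cat]],
               n_trials = unname(es$n[cat])))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a scenario config to/from YAML
#'
#' Kernels are stored as lag/value vectors and the bound function by its
#' kind and parameters, so a round-trip reproduces an equivalent config.
#'
#' @param config a [scenario_config()].
#' @param path YAML file path.
#' @return `read_config` returns a [scenario_config()].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$bound <- c(list(kind = attr(config$bound, "kind")),
               attr(config$bound, "params"))
  for (k in c("s_kernel", "r_kernel")) {
    if (!is.null(x[[k]]))
      x[[k]] <- list(lags = x[[k]]$lags, values = x[[k]]$values, fs = x[[k]]$fs)
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  bound <- bound_from_params(x$bound$kind,
                             x$bound[setdiff(names(x$bound), "kind")])
  kern <- function(k) if (is.null(k)) NULL else
    waveform_kernel(k$lags, k$values, k$fs)
  scenario_config(scenario = x$scenario, n_trials = x$n_trials, fs = x$fs,
                  rt = x$rt, iti = x$iti,
                  s_kernel = kern(x$s_kernel), r_kernel = kern(x$r_kernel),
                  ramp = x$ramp, bound = bound, ddm = x$ddm,
                  sensor_noise_sd = x$sensor_noise_sd, pad = x$pad,
                  seed = x$seed)
}

#' Write a full run to disk
#'
#' Emits, per panel, the key waveforms as TSV, the resolved config as YAML,
#' and one `summary.json` with the headline effects and the jitter table.
#'
#' @param run a [run_all()] result.
#' @param out_dir output directory (created if needed).
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (p in c("a", "b", "c", "d", "e", "f")) {
    rep <- run[[p]]
    write_config(rep$config, file.path(out_dir, paste0("panel_", p, "_config.yaml")))
    es <- rep$resp_locked %||% rep$resp_locked_corrected %||% rep$s_kernels
    if (!is.null(es))
      write_erp_set(es, file.path(out_dir, paste0("panel_", p, "_waveforms.tsv")))
  }
  utils::write.table(run$jitter$summary,
                     file.path(out_dir, "jitter_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = run$seed, summary = run$summary,
                            jitter = run$jitter$summary),
                       file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
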
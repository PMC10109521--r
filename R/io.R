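# File formats and the pipeline driver. Spike trains travel as a single
# columnar CSV (unit_id, trial, time_s) with "#"-prefixed header metadata;
# LFP travels as a directory of per-trial plain-text matrices plus a YAML
# meta file. Results are written as JSON (scalars) plus CSV (vectors).

#' Write spike trains to a columnar CSV file
#'
#' One row per spike with columns `unit_id`, `trial`, `time_s` (the left
#' edge of the spike's sample). Sampling rate and trial lengths are stored
#' in `#`-prefixed header lines, so the file round-trips losslessly through
#' [read_spikes()].
#'
#' @param spikes a [spike_trains()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_trains"))
  rows <- list()
  for (m in seq_along(spikes$times)) {
    for (k in seq_len(spikes$n_trials)) {
      idx <- spikes$times[[m]][[k]]
      if (length(idx))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          unit_id = spikes$units[m], trial = k,
          time_s = (idx - 1L) / spikes$fs)
    }
  }
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(unit_id = character(), trial = integer(),
                           time_s = numeric())
  hdr <- c(sprintf("# fs: %.10g", spikes$fs),
           sprintf("# trial_samples: %s",
                   paste(spikes$trial_samples, collapse = " ")),
           sprintf("# units: %s", paste(spikes$units, collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("unit_id,trial,time_s", con)
  if (nrow(dt))
    writeLines(sprintf("%s,%d,%.10g", dt$unit_id, dt$trial, dt$time_s), con)
  invisible(path)
}

#' Read spike trains from a columnar CSV file
#'
#' Validates the schema strictly: every row must have a known unit, a trial
#' index within range, and a non-negative time within the trial; violations
#' are reported with their row number.
#'
#' @param path a file written by [write_spikes()].
#' @return a [spike_trains()] object.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("spike file missing '# ", key, ":' header: ", path)
    strsplit(sub(paste0("^# ", key, ": *"), "", ln[1L]), " +")[[1L]]
  }
  fs <- as.numeric(get_meta("fs"))
  trial_samples <- as.integer(get_meta("trial_samples"))
  units <- get_meta("units")
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1L] != "unit_id,trial,time_s")
    stop("spike file must have header row 'unit_id,trial,time_s': ", path)
  body <- body[-1L]
  if (!length(body)) stop("empty spike file (no spikes): ", path)
  parts <- data.table::fread(text = body, header = FALSE,
                             col.names = c("unit_id", "trial", "time_s"),
                             colClasses = list(character = 1L))
  n_trials <- length(trial_samples)
  bad_unit <- which(!(parts$unit_id %in% units))
  if (length(bad_unit))
    stop("unknown unit_id '", parts$unit_id[bad_unit[1L]], "' at data row ",
         bad_unit[1L])
  bad_trial <- which(parts$trial < 1L | parts$trial > n_trials)
  if (length(bad_trial))
    stop("trial index out of range [1, ", n_trials, "] at data row ",
         bad_trial[1L])
  idx_max <- trial_samples[parts$trial]
  x <- parts$time_s * fs
  i0 <- floor(x)
  samp <- as.integer(i0 + (x - i0 > 0.5) + 1L)
  bad_time <- which(parts$time_s < 0 | samp > idx_max)
  if (length(bad_time))
    stop("spike time ", parts$time_s[bad_time[1L]],
         " s beyond trial length at data row ", bad_time[1L])
  times <- lapply(units, function(u) {
    sel_u <- parts$unit_id == u
    lapply(seq_len(n_trials), function(k) sort(samp[sel_u & parts$trial == k]))
  })
  spike_trains(times, trial_samples, fs, units)
}

#' Write a multi-trial LFP to a directory of plain-text matrices
#'
#' Creates `meta.yml` (sampling rate, channel ids, coordinates) and one
#' `trial_###.csv` per trial (channels as rows, samples as columns, no
#' header).
#'
#' @param lfp a [raw_lfp()] object.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_lfp <- function(lfp, path) {
  stopifnot(inherits(lfp, "raw_lfp"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = lfp$fs, n_trials = length(lfp$trials),
               channel_ids = as.character(lfp$channel_ids))
  if (!is.null(lfp$coords)) meta$coords <- apply(lfp$coords, 1L, as.numeric,
                                                 simplify = FALSE)
  yaml::write_yaml(meta, file.path(path, "meta.yml"))
  for (k in seq_along(lfp$trials)) {
    data.table::fwrite(data.table::as.data.table(lfp$trials[[k]]),
                       file.path(path, sprintf("trial_%03d.csv", k)),
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a multi-trial LFP written by [write_lfp()]
#'
#' @param path directory containing `meta.yml` and `trial_###.csv` files.
#' @return a [raw_lfp()] object.
#' @export
read_lfp <- function(path) {
  meta_path <- file.path(path, "meta.yml")
  if (!file.exists(meta_path)) stop("missing ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  files <- sort(list.files(path, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no trial_###.csv files in ", path)
  trials <- lapply(files, function(f)
    as.matrix(data.table::fread(f, header = FALSE)))
  trials <- lapply(trials, function(m) {
    dimnames(m) <- NULL
    m
  })
  coords <- if (!is.null(meta$coords))
    do.call(rbind, lapply(meta$coords, as.numeric)) else NULL
  raw_lfp(trials, fs = meta$fs, channel_ids = meta$channel_ids,
          coords = coords)
}

#' Write GPLA results (and optional significance report) to disk
#'
#' Produces `result.json` with the scalar summaries and convention flags,
#' and `vectors.csv` with the complex LFP/spike vector coefficients and the
#' singular spectrum.
#'
#' @param result a `gpla_result`.
#' @param report optional `significance_report`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_result <- function(result, report = NULL, path) {
  stopifnot(inherits(result, "gpla_result"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    gplv = result$gplv, phi_d = result$phi_d,
    complex_gplv = c(Re(result$complex_gplv), Im(result$complex_gplv)),
    band = result$band, mode = result$mode, whitened = result$whitened,
    n_c = result$n_c, n_s = result$n_s,
    conventions = result$conventions
  )
  if (result$mode == "plv") out$gplv_normalized <- normalize_gplv(result)
  if (!is.null(report)) {
    out$significance <- list(
      method = report$method, p_value = report$p_value,
      significant = report$significant, threshold = report$threshold,
      n_surrogates = report$n_surrogates,
      jitter_window = report$jitter_window, seed = report$seed,
      n_significant = report$n_significant
    )
  }
  jsonlite::write_json(out, file.path(path, "result.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  nv <- max(result$n_c, result$n_s, length(result$spectrum))
  pad <- function(x, n) c(x, rep(NA, n - length(x)))
  u <- result$lfp_vector
  v <- result$spike_vector
  dt <- data.table::data.table(
    index = seq_len(nv),
    lfp_re = pad(Re(u), nv), lfp_im = pad(Im(u), nv),
    spike_re = pad(Re(v), nv), spike_im = pad(Im(v), nv),
    singular_value = pad(result$spectrum, nv)
  )
  data.table::fwrite(dt, file.path(path, "vectors.csv"))
  invisible(path)
}

default_config <- function() {
  list(
    bands = list(c(11, 15.5)),
    mode = "plv",
    whiten = FALSE,
    variance_threshold = 0.99,
    edge_margin_cycles = 3,
    min_spikes = 50L,
    significance = list(method = "surrogate", n_surrogates = 100L,
                        jitter = "interval", level = 0.05),
    seed = 1L
  )
}

#' Read / write a pipeline configuration
#'
#' A plain YAML key/value file is the single source of truth for a run;
#' fields missing from the file take the documented defaults. The effective
#' configuration is always written next to the results by [run_pipeline()].
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (k in names(cfg)) base[[k]] <- cfg[[k]]
  if (!is.list(base$bands[[1]])) {
    # yaml reads "bands: [[11, 15.5]]" as list of vectors already; accept a
    # single flat band too
    if (is.numeric(base$bands) && length(base$bands) == 2L)
      base$bands <- list(base$bands)
  }
  base$bands <- lapply(base$bands, as.numeric)
  base
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full GPLA pipeline from data to results
#'
#' Sequences preprocessing, coupling-matrix construction, SVD, phase
#' conventions and significance testing for each requested frequency band,
#' with full determinism under the configured seed. When `out_dir` is set,
#' per-band results, significance reports and the effective configuration
#' are written there.
#'
#' @param lfp a [raw_lfp()] or a path readable by [read_lfp()].
#' @param spikes a [spike_trains()] or a path readable by [read_spikes()].
#' @param config configuration list (see [read_config()]) or a YAML path;
#'   omitted fields take defaults.
#' @param out_dir optional output directory.
#' @return named list, one entry per band, each with `result` and `report`.
#' @export
run_pipeline <- function(lfp, spikes, config = list(), out_dir = NULL) {
  if (is.character(lfp)) lfp <- read_lfp(lfp)
  if (is.character(spikes)) spikes <- read_spikes(spikes)
  if (is.character(config)) config <- read_config(config)
  base <- default_config()
  for (k in names(config)) base[[k]] <- config[[k]]
  config <- base
  if (is.numeric(config$bands) && length(config$bands) == 2L)
    config$bands <- list(config$bands)
  set.seed(config$seed)
  out <- list()
  for (band in config$bands) {
    band <- as.numeric(band)
    fit <- gpla(lfp, spikes, band = band, mode = config$mode,
                whiten = config$whiten,
                variance_threshold = config$variance_threshold,
                edge_margin_cycles = config$edge_margin_cycles,
                min_spikes = config$min_spikes)
    sig <- config$significance
    report <- if (identical(sig$method, "analytic")) {
      rep_ <- analytic_test(fit$coupling)
      fit$result$n_significant <- rep_$n_significant
      rep_
    } else if (identical(sig$method, "surrogate")) {
      an <- bandpass_analytic(lfp, band)
      tr <- trim_edges(an, spikes, cycles = config$edge_margin_cycles)
      surrogate_test(tr$spikes, tr$lfp,
                     n_surrogates = sig$n_surrogates %||% 100L,
                     jitter = sig$jitter %||% "interval",
                     mode = config$mode, min_spikes = config$min_spikes)
    } else NULL
    key <- sprintf("band_%g_%g", band[1L], band[2L])
    out[[key]] <- list(result = fit$result, report = report)
    if (!is.null(out_dir)) {
      write_result(fit$result, report, file.path(out_dir, key))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config_effective.yml"))
  }
  out
}
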
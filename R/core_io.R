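#' Read a continuous recording from disk
#'
#' Supported formats are EDF (16-bit European Data Format) and a delimited
#' text dialect: one header row of channel labels, one row per sample,
#' comma-separated, with the sampling rate carried in a JSON sidecar file
#' `<path>.json` (written by [write_recording()]) or supplied via `rate`.
#' Sample values are microvolts; time 0 is the first sample and sample
#' indices are 0-based throughout the package.
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`.
#' @param rate sampling rate in Hz, required for CSV when no sidecar exists.
#' @return an [recording()] object.
#' @export
read_recording <- function(path, format = c("edf", "csv"), rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  earbci_log("read_recording(", path, ", format=", format, ")")
  if (format == "edf") return(read_edf(path))
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("failed to parse CSV ", path, ": ",
                                          conditionMessage(e)))
  if (ncol(df) < 1L || nrow(df) < 1L) stop("empty CSV recording: ", path)
  sidecar <- paste0(path, ".json")
  montage <- NULL
  if (is.null(rate) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rate <- meta$rate
    montage <- meta$montage
  }
  if (is.null(rate)) {
    stop("CSV recording ", path, " has no rate: supply `rate` or a ",
         sidecar, " sidecar")
  }
  recording(t(as.matrix(df)), rate = rate, channel_labels = names(df),
            montage = montage)
}

#' Write a continuous recording to disk
#'
#' EDF output quantizes to 16 bits over the per-channel physical range (or a
#' fixed `phys_range`, e.g. `c(-1000, 1000)` microvolts full scale); the
#' round-trip error is at most one quantization step. CSV output is exact to
#' printed precision and writes a JSON sidecar `<path>.json` holding the rate
#' and montage.
#'
#' @param rec an [recording()] object.
#' @param path destination file path.
#' @param format `"edf"` or `"csv"`.
#' @param phys_range optional length-2 physical range (microvolts) applied to
#'   all channels in EDF output; default is per-channel data range.
#' @return the path, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "csv"),
                            phys_range = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  earbci_log("write_recording(", path, ", format=", format, ", ",
             nrow(rec$data), "x", ncol(rec$data), ")")
  if (format == "edf") {
    write_edf(rec, path, phys_range = phys_range)
  } else {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_labels
    ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                   error = function(e) stop("cannot write ", path, ": ",
                                            conditionMessage(e)))
    jsonlite::write_json(list(rate = rec$rate, montage = rec$montage),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Cut fixed-length epochs around stimulus events
#'
#' Trial `i` covers samples `[round(onset_i * rate), round(onset_i * rate) +
#' round(window_s * rate))` — a half-open window with onsets rounded to the
#' nearest sample. Class labels, and the per-class stimulus table, are taken
#' from the event table.
#'
#' @param rec an [recording()].
#' @param events an [event_table()].
#' @param window_s epoch length in seconds.
#' @param blocks optional block index per event for cross-validation.
#' @return a [trial_set()] with one trial per event.
#' @export
slice_epochs <- function(rec, events, window_s, blocks = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0)
  n_ev <- nrow(events)
  wlen <- round(window_s * rec$rate)
  starts <- round(events$onset_s * rec$rate)      # 0-based start sample
  bad <- which(starts + wlen > ncol(rec$data) | starts < 0)
  if (length(bad)) {
    stop("epoch window exceeds recording for events: ",
         paste(bad, collapse = ", "))
  }
  earbci_log("slice_epochs: ", n_ev, " events, window ", window_s, " s (",
             wlen, " samples)")
  dat <- array(0, dim = c(n_ev, nrow(rec$data), wlen))
  for (i in seq_len(n_ev)) {
    dat[i, , ] <- rec$data[, starts[i] + seq_len(wlen), drop = FALSE]
  }
  classes <- sort(unique(events$class_index))
  stim <- lapply(seq_len(max(c(events$class_index, 0))), function(k) {
    row <- match(k, events$class_index)
    if (is.na(row)) {
      stimulus_spec(1, 0, window_s)     # placeholder for unused index
    } else {
      stimulus_spec(events$frequency_hz[row], events$phase_rad[row],
                    if (is.na(events$duration_s[row])) window_s
                    else events$duration_s[row])
    }
  })
  if (n_ev == 0L) {
    return(trial_set(array(0, dim = c(0, nrow(rec$data), wlen)), rec$rate,
                     integer(0), list(), rec$channel_labels))
  }
  trial_set(dat, rec$rate, events$class_index, stim, rec$channel_labels,
            blocks = blocks)
}

# ---------------------------------------------------------------------------
# configuration

config_defaults <- function() {
  list(
    seed = 1L,
    simulation = list(
      ssvep = list(rate = 250, trial_s = 4, n_blocks = 6, n_harmonics = 3,
                   noise_rms_uV = 2, one_over_f_exponent = 1,
                   alpha_center_hz = 10, alpha_rms_uV = 2, alpha_on = FALSE,
                   n_channels = 10),
      cocktail = list(trial_s = 60, env_rate = 128, pulse_rate_hz = 4,
                      noise_rms_uV = 0.3, n_trials = 24, n_channels = 10)
    ),
    preprocessing = list(band_lo_hz = 0.5, band_hi_hz = 90, rate_out = 250,
                         ptp_limit_uV = 200, flat_limit_uV = 0.5,
                         reject_threshold = 4),
    decoder = list(method = "trca", ensemble = TRUE, n_subbands = 5,
                   n_harmonics = 5, n_train_blocks = 5),
    metrics = list(snr_K = 4, gaze_shift_s = 0.5),
    aad = list(forward_lags_ms = c(0, 500), backward_lags_ms = c(0, 250),
               lambda_grid = c(1e-4, 1e-2, 1), env_rate = 128)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stop("configuration key ", full,
                                      " must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("configuration error: ", what)
  chk(cfg$metrics$snr_K %% 2 == 0 && cfg$metrics$snr_K >= 2,
      "metrics.snr_K must be an even integer >= 2 (the narrow-band SNR sums k = 1..K/2 on both sides)")
  chk(cfg$metrics$gaze_shift_s >= 0, "metrics.gaze_shift_s must be >= 0")
  with(cfg$preprocessing, {
    chk(band_lo_hz > 0 && band_hi_hz > band_lo_hz,
        "preprocessing band edges must satisfy 0 < lo < hi")
    chk(ptp_limit_uV > 0 && flat_limit_uV > 0,
        "preprocessing amplitude limits must be positive")
  })
  with(cfg$simulation$ssvep, {
    chk(rate > 0 && trial_s > 0 && n_blocks >= 1 && n_harmonics >= 1,
        "simulation.ssvep sizes must be positive")
    chk(noise_rms_uV >= 0 && alpha_rms_uV >= 0,
        "simulation.ssvep noise amplitudes must be >= 0")
  })
  with(cfg$simulation$cocktail, {
    chk(trial_s > 0 && env_rate > 0 && n_trials >= 1,
        "simulation.cocktail sizes must be positive")
    chk(pulse_rate_hz < env_rate / 2,
        "simulation.cocktail.pulse_rate_hz must be below env_rate/2")
  })
  chk(cfg$decoder$n_subbands >= 1 && cfg$decoder$n_harmonics >= 1,
      "decoder sub-band and harmonic counts must be >= 1")
  invisible(cfg)
}

#' Load and validate a pipeline configuration
#'
#' The configuration is YAML with sections `simulation` (`ssvep`,
#' `cocktail`), `preprocessing`, `decoder`, `metrics` and `aad`; every
#' numeric parameter is named and range-checked, omitted keys take their
#' defaults, and unknown keys raise an error naming the key. The fully
#' resolved configuration is echoed to the log. `load_config()` with no path
#' (or an empty file) returns the all-defaults configuration.
#'
#' @param path path to a YAML configuration file, or `NULL` for defaults.
#' @return the resolved configuration as a named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such configuration file: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  earbci_log("resolved config: ", jsonlite::toJSON(cfg, auto_unbox = TRUE))
  cfg
}
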
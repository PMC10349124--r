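#' Continuous multi-channel EEG recording
#'
#' The basic container for continuous data: a channels-by-samples matrix in
#' microvolts with a sampling rate and labelled montage. Montage tags
#' classify each channel as in-ear (left/right), mastoid, occipital or other,
#' following the study montage (in-ear L1--L5 and R1--R5, mastoids M1/M2,
#' occipital OZ); tags are inferred from labels when not given.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in samples per second; must be positive.
#' @param channel_labels character vector of unique channel names, one per
#'   row of `data`. Defaults to rownames of `data` or `ch1..chN`.
#' @param montage optional character vector of montage tags (one per
#'   channel) from `in_ear_left`, `in_ear_right`, `mastoid`, `occipital`,
#'   `other`; inferred from `channel_labels` when `NULL`.
#' @return an object of class `eeg_recording` with elements `data`, `rate`,
#'   `channel_labels`, `montage`.
#' @export
recording <- function(data, rate, channel_labels = NULL, montage = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(nrow(data)))
    }
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length (", length(channel_labels),
         ") must equal channel count (", nrow(data), ")")
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique")
  }
  if (is.null(montage)) montage <- montage_from_labels(channel_labels)
  if (length(montage)) {
    montage <- match.arg(montage, montage_tags(), several.ok = TRUE)
  }
  if (length(montage) != nrow(data)) {
    stop("montage length must equal channel count")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, rate = as.numeric(rate),
         channel_labels = channel_labels, montage = montage),
    class = "eeg_recording"
  )
}

montage_tags <- function() {
  c("in_ear_left", "in_ear_right", "mastoid", "occipital", "other")
}

#' Infer montage tags from channel labels
#'
#' `L1..L5` map to the left in-ear group, `R1..R5` to the right, `M1`/`M2`
#' to the mastoids and `OZ`/`Oz` to the occipital site; anything else is
#' tagged `other`.
#'
#' @param labels character vector of channel labels.
#' @return character vector of montage tags.
#' @export
montage_from_labels <- function(labels) {
  tag1 <- function(lab) {
    if (grepl("^L[1-5]$", lab)) return("in_ear_left")
    if (grepl("^R[1-5]$", lab)) return("in_ear_right")
    if (grepl("^M[12]$", lab)) return("mastoid")
    if (toupper(lab) == "OZ") return("occipital")
    "other"
  }
  vapply(as.character(labels), tag1, character(1), USE.NAMES = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$rate

#' Stimulus specification for one SSVEP target
#'
#' @param frequency_hz flicker frequency in Hz (> 0).
#' @param phase_rad initial phase in radians.
#' @param duration_s stimulation duration in seconds (> 0).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(frequency_hz, phase_rad = 0, duration_s = 1) {
  stopifnot(frequency_hz > 0, duration_s > 0)
  structure(list(frequency_hz = frequency_hz, phase_rad = phase_rad,
                 duration_s = duration_s), class = "stimulus_spec")
}

#' Stimulus event table
#'
#' One row per stimulus presentation: onset from the start of the recording,
#' a 1-based class index into the class table, and the stimulus parameters.
#'
#' @param onset_s numeric, seconds from recording start; must be
#'   non-decreasing.
#' @param class_index integer class labels (>= 1).
#' @param frequency_hz,phase_rad,duration_s stimulus parameters, recycled.
#' @return a `data.frame` of class `event_table`.
#' @export
event_table <- function(onset_s, class_index, frequency_hz = NA_real_,
                        phase_rad = 0, duration_s = NA_real_) {
  if (length(onset_s) && is.unsorted(onset_s)) {
    stop("event onsets must be non-decreasing")
  }
  if (length(class_index) && any(class_index < 1)) {
    stop("class_index must be >= 1")
  }
  n <- length(onset_s)
  df <- data.frame(onset_s = as.numeric(onset_s),
                   class_index = rep_len(as.integer(class_index), n),
                   frequency_hz = rep_len(as.numeric(frequency_hz), n),
                   phase_rad = rep_len(as.numeric(phase_rad), n),
                   duration_s = rep_len(as.numeric(duration_s), n))
  class(df) <- c("event_table", "data.frame")
  df
}

#' Epoched trial set
#'
#' Trials cut from a continuous recording: a trial x channel x sample array
#' with per-trial class labels, the per-class stimulus table, and (when the
#' trials come from a blocked design) block indices used by
#' leave-one-block-out cross-validation.
#'
#' @param data numeric array, trial x channel x sample.
#' @param rate sampling rate in Hz.
#' @param labels integer class index per trial (1-based into `stimuli`).
#' @param stimuli list of [stimulus_spec()] objects, one per class.
#' @param channel_labels character vector of channel names.
#' @param blocks optional integer block index per trial.
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(data, rate, labels, stimuli, channel_labels = NULL,
                      blocks = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, rate > 0)
  n_trial <- dim(data)[1]
  if (length(labels) != n_trial) stop("one label per trial required")
  labels <- as.integer(labels)
  if (n_trial > 0 && (any(labels < 1) || any(labels > length(stimuli)))) {
    stop("every label must index a stimulus in `stimuli`")
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channel_labels) != dim(data)[2]) {
    stop("channel_labels length must equal channel count")
  }
  if (!is.null(blocks) && length(blocks) != n_trial) {
    stop("one block index per trial required")
  }
  structure(
    list(data = data, rate = as.numeric(rate), labels = labels,
         stimuli = stimuli, channel_labels = as.character(channel_labels),
         blocks = if (is.null(blocks)) NULL else as.integer(blocks)),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz, %d classes\n",
              d[1], d[2], d[3], x$rate, length(x$stimuli)))
  invisible(x)
}

#' Number of trials in a trial set
#' @param ts a `trial_set`.
#' @return trial count.
#' @export
n_trials <- function(ts) dim(ts$data)[1]

#' Stimulus envelope at the EEG rate
#'
#' Holds a single stimulus feature time series, here the onset envelope used
#' for auditory attention decoding. Onset envelopes are nonnegative by
#' construction.
#'
#' @param values numeric vector of envelope samples.
#' @param rate envelope sampling rate in Hz (matches the AAD EEG rate).
#' @return an object of class `envelope`.
#' @export
envelope <- function(values, rate) {
  stopifnot(is.numeric(values), rate > 0)
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 duration_s = length(values) / rate),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d samples @ %g Hz (%.2f s)\n",
              length(x$values), x$rate, x$duration_s))
  invisible(x)
}
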
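# Filtering and resampling sit on the `signal` package (Butterworth designs,
# forward-backward filtering, polyphase resampling). The band-pass is
# realized as a high-pass/low-pass cascade: at EEG rates the lower edge
# (e.g. 0.5 Hz of the 0.5-90 Hz band at 250 Hz) is a tiny normalized
# frequency, where a direct transfer-function band-pass is numerically
# fragile but the cascade is not.

bp_matrix <- function(data, rate, lo_hz, hi_hz, order = 4) {
  nyq <- rate / 2
  if (!(lo_hz > 0 && hi_hz > lo_hz)) stop("band edges must satisfy 0 < lo < hi")
  if (hi_hz >= nyq) stop("upper band edge ", hi_hz,
                         " Hz must be below the Nyquist frequency ", nyq, " Hz")
  hp <- signal::butter(order, lo_hz / nyq, type = "high")
  lp <- signal::butter(order, hi_hz / nyq, type = "low")
  out <- data
  for (i in seq_len(nrow(data))) {
    # remove the mean first: the high-pass kills DC anyway, and centred
    # input keeps filtfilt's edge transients small
    y <- signal::filtfilt(hp, data[i, ] - mean(data[i, ]))
    out[i, ] <- signal::filtfilt(lp, y)
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Butterworth high-pass/low-pass cascade of the given order, applied
#' forward and backward ([signal::filtfilt()]) so the net filter has zero
#' phase (no group delay) and the effective roll-off is twice the design
#' order. With the default 4th order the stopband attenuation exceeds 40 dB
#' one octave outside the band edges. Shape and rate are unchanged. The
#' study bands are 0.5--90 Hz for SSVEP data and 2--8 Hz (delta/theta
#' anti-aliasing) for auditory-attention data.
#'
#' @param rec an [recording()], or a channels x samples matrix (then `rate`
#'   is required).
#' @param lo_hz,hi_hz band edges in Hz, `0 < lo < hi < rate/2`.
#' @param order filter order per section (default 4).
#' @param rate sampling rate, only for matrix input.
#' @return object of the same type as `rec`, filtered.
#' @export
bandpass <- function(rec, lo_hz, hi_hz, order = 4, rate = NULL) {
  if (inherits(rec, "eeg_recording")) {
    earbci_log("bandpass ", lo_hz, "-", hi_hz, " Hz, order ", order, ", ",
               nrow(rec$data), "x", ncol(rec$data))
    rec$data <- bp_matrix(rec$data, rec$rate, lo_hz, hi_hz, order)
    return(rec)
  }
  if (is.null(rate)) stop("matrix input requires `rate`")
  if (is.vector(rec)) rec <- matrix(rec, nrow = 1)
  bp_matrix(rec, rate, lo_hz, hi_hz, order)
}

#' Resample a recording to a lower rate
#'
#' Rational-ratio polyphase resampling with an anti-aliasing low-pass
#' (zero-phase Butterworth at 90\% of the target Nyquist) applied before
#' decimation. Only downsampling is supported; the study decimates to
#' 250 Hz (visual) and 128 Hz (auditory).
#'
#' @param rec an [recording()].
#' @param target_rate new rate in Hz, `<= rec$rate`.
#' @return the resampled [recording()].
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate) {
    stop("no upsampling path: target rate ", target_rate,
         " exceeds recording rate ", rec$rate)
  }
  if (target_rate == rec$rate) return(rec)
  earbci_log("resample ", rec$rate, " -> ", target_rate, " Hz")
  frac <- .ratio(target_rate / rec$rate)
  nyq <- rec$rate / 2
  lp <- signal::butter(6, 0.9 * (target_rate / 2) / nyq, type = "low")
  n_out <- round(ncol(rec$data) * target_rate / rec$rate)
  out <- matrix(0, nrow = nrow(rec$data), ncol = n_out)
  for (i in seq_len(nrow(rec$data))) {
    y <- signal::filtfilt(lp, rec$data[i, ])
    z <- signal::resample(y, frac[1], frac[2])
    out[i, ] <- z[seq_len(n_out)]
  }
  recording(out, rate = target_rate, channel_labels = rec$channel_labels,
            montage = rec$montage)
}

# small-denominator rational approximation of a rate ratio
.ratio <- function(x, max_den = 1024L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("rate ratio ", x, " has no small rational form")
}

#' Flag bad channels in one epoch
#'
#' A channel is bad if its peak-to-peak amplitude exceeds `ptp_limit_uV`
#' (movement/electrode artifact) or falls below `flat_limit_uV` (flat or
#' disconnected). This threshold rule is the package's documented
#' replacement for data-driven artifact search.
#'
#' @param epoch channels x samples matrix, microvolts.
#' @param ptp_limit_uV upper peak-to-peak limit (default 200).
#' @param flat_limit_uV lower peak-to-peak limit (default 0.5).
#' @return integer vector of bad channel indices (possibly empty).
#' @export
detect_bad_channels <- function(epoch, ptp_limit_uV = 200, flat_limit_uV = 0.5) {
  stopifnot(ptp_limit_uV > 0, flat_limit_uV > 0)
  ptp <- apply(epoch, 1, function(x) diff(range(x)))
  which(ptp > ptp_limit_uV | ptp < flat_limit_uV)
}

#' Reject or repair artifact-laden epochs
#'
#' Applies the study's cleaning rule to every epoch: channels are flagged by
#' [detect_bad_channels()]; an epoch with more than `reject_threshold` bad
#' channels (more than 4 of 10 under the default) is dropped, otherwise each
#' bad channel is replaced by the mean of that epoch's good channels. For
#' channel counts other than 10 the default threshold scales as
#' `ceiling(0.4 * n_channels)` (logged).
#'
#' @param trials a [trial_set()].
#' @param ptp_limit_uV,flat_limit_uV per-channel limits, see
#'   [detect_bad_channels()].
#' @param reject_threshold epochs with strictly more bad channels than this
#'   are rejected; `NULL` for the scaled default.
#' @return list with `trials` (cleaned [trial_set()]) and `report`, a data
#'   frame with per-epoch `n_bad`, `bad_channels` (semicolon-joined labels)
#'   and `action` (`kept`, `interpolated` or `rejected`), plus attributes
#'   `n_rejected` and `n_interpolated`.
#' @export
clean_epochs <- function(trials, ptp_limit_uV = 200, flat_limit_uV = 0.5,
                         reject_threshold = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  n_ch <- dim(trials$data)[2]
  if (is.null(reject_threshold)) {
    reject_threshold <- ceiling(0.4 * n_ch)
    if (n_ch != 10) {
      earbci_log("clean_epochs: ", n_ch, " channels; reject threshold scaled to ",
                 reject_threshold)
    }
  }
  n <- n_trials(trials)
  actions <- character(n)
  n_bad <- integer(n)
  bad_lab <- character(n)
  keep <- logical(n)
  dat <- trials$data
  for (i in seq_len(n)) {
    ep <- dat[i, , , drop = TRUE]
    if (is.vector(ep)) ep <- matrix(ep, nrow = n_ch)
    bad <- detect_bad_channels(ep, ptp_limit_uV, flat_limit_uV)
    n_bad[i] <- length(bad)
    bad_lab[i] <- paste(trials$channel_labels[bad], collapse = ";")
    if (length(bad) > reject_threshold || length(bad) == n_ch) {
      actions[i] <- "rejected"
      keep[i] <- FALSE
    } else if (length(bad) > 0L) {
      good <- setdiff(seq_len(n_ch), bad)
      fill <- colMeans(ep[good, , drop = FALSE])
      for (b in bad) dat[i, b, ] <- fill
      actions[i] <- "interpolated"
      keep[i] <- TRUE
    } else {
      actions[i] <- "kept"
      keep[i] <- TRUE
    }
  }
  report <- data.frame(epoch = seq_len(n), n_bad = n_bad,
                       bad_channels = bad_lab, action = actions,
                       stringsAsFactors = FALSE)
  attr(report, "n_rejected") <- sum(actions == "rejected")
  attr(report, "n_interpolated") <- sum(actions == "interpolated")
  if (!any(keep) && n > 0L) warning("clean_epochs: every epoch was rejected")
  out <- trial_set(dat[keep, , , drop = FALSE], trials$rate,
                   trials$labels[keep], trials$stimuli,
                   trials$channel_labels,
                   blocks = if (is.null(trials$blocks)) NULL
                            else trials$blocks[keep])
  earbci_log("clean_epochs: ", attr(report, "n_rejected"), " rejected, ",
             attr(report, "n_interpolated"), " interpolated of ", n)
  list(trials = out, report = report)
}
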
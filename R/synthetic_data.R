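# Synthetic-EEG generators. These define the study conditions used by the
# tests and analysis scripts: SSVEP trials with fundamental-plus-harmonic
# structure over 1/f noise, eyes-closed alpha rest, and two-speaker
# cocktail-party trials built as ground-truth TRFs convolved with onset
# envelopes. All generators are deterministic given their config and seed.

#' The 9-target SSVEP frequency table
#'
#' Nine flicker frequencies from 8 to 12 Hz in 0.5 Hz steps, all at phase 0.
#'
#' @param duration_s stimulation duration per trial (default 8 s).
#' @return list of [stimulus_spec()] objects.
#' @export
class_table_9 <- function(duration_s = 8) {
  lapply(seq(8, 12, by = 0.5), stimulus_spec,
         phase_rad = 0, duration_s = duration_s)
}

#' The 40-target joint frequency/phase grid
#'
#' Frequencies 8.0--15.8 Hz in 0.2 Hz steps with a phase increment of
#' 0.35 pi per class, the joint frequency/phase coding convention of
#' 40-target speller work.
#'
#' @param duration_s stimulation duration per trial (default 6 s).
#' @return list of 40 [stimulus_spec()] objects.
#' @export
class_table_40 <- function(duration_s = 6) {
  freqs <- seq(8, 15.8, by = 0.2)
  lapply(seq_along(freqs), function(k) {
    stimulus_spec(freqs[k], phase_rad = ((k - 1) * 0.35 * pi) %% (2 * pi),
                  duration_s = duration_s)
  })
}

#' Default harmonic mixing matrix
#'
#' Channel x harmonic amplitude matrix in microvolts. In-ear channels get a
#' 2nd-harmonic emphasis (A2/A1 = 1.2) while occipital channels follow the
#' classic descending profile (A2/A1 = 0.6); higher harmonics decay
#' geometrically. A fixed deterministic per-channel gain profile (0.8--1.2)
#' emulates electrode-to-electrode sensitivity differences.
#'
#' @param channel_labels montage labels; tags via [montage_from_labels()].
#' @param n_harmonics number of harmonics.
#' @param a1_uV fundamental amplitude in microvolts (default 1).
#' @return channels x harmonics matrix.
#' @export
default_mixing <- function(channel_labels, n_harmonics = 3, a1_uV = 1) {
  tags <- montage_from_labels(channel_labels)
  n_ch <- length(channel_labels)
  gains <- 0.8 + 0.4 * (seq_len(n_ch) - 1) / max(1, n_ch - 1)
  mix <- matrix(0, n_ch, n_harmonics)
  for (c in seq_len(n_ch)) {
    r2 <- if (tags[c] %in% c("in_ear_left", "in_ear_right")) 1.2 else 0.6
    amps <- a1_uV * c(1, r2, r2 * 0.4^(seq_len(max(0, n_harmonics - 2))))
    mix[c, ] <- gains[c] * amps[seq_len(n_harmonics)]
  }
  rownames(mix) <- channel_labels
  mix
}

#' SSVEP simulation configuration
#'
#' Bundles the stimulus table, harmonic mixing, noise model and trial
#' structure. Defaults reproduce the desk-scale study conditions: the
#' 9-class 8--12 Hz table, 3 harmonics with in-ear 2nd-harmonic emphasis,
#' 1 uV fundamentals, 1/f noise of exponent 1 at 2 uV RMS ("moderate"
#' noise), 250 Hz rate, 4 s trials, 6 blocks, 10 in-ear channels.
#'
#' @param class_table list of [stimulus_spec()] (default [class_table_9()]).
#' @param n_harmonics harmonics per stimulus (>= 1).
#' @param channel_labels channel names (montage inferred).
#' @param mixing channels x harmonics amplitude matrix in microvolts;
#'   default [default_mixing()].
#' @param noise_rms_uV RMS of the 1/f background per channel.
#' @param one_over_f_exponent spectral exponent of the background noise.
#' @param alpha list `(center_hz, rms_uV, on)` controlling the resting
#'   alpha component (off by default during SSVEP trials).
#' @param rate sampling rate in Hz (default 250).
#' @param trial_s trial length in seconds (default 4).
#' @param n_blocks number of stimulation blocks (default 6).
#' @param seed RNG seed.
#' @return validated list of class `ssvep_sim_config`.
#' @export
ssvep_sim_config <- function(class_table = class_table_9(),
                             n_harmonics = 3,
                             channel_labels = c(paste0("L", 1:5), paste0("R", 1:5)),
                             mixing = NULL,
                             noise_rms_uV = 2,
                             one_over_f_exponent = 1,
                             alpha = list(center_hz = 10, rms_uV = 2, on = FALSE),
                             rate = 250, trial_s = 4, n_blocks = 6, seed = 1) {
  stopifnot(n_harmonics >= 1, rate > 0, trial_s > 0, n_blocks >= 1,
            noise_rms_uV >= 0)
  if (is.null(mixing)) mixing <- default_mixing(channel_labels, n_harmonics)
  if (!is.matrix(mixing) ||
      nrow(mixing) != length(channel_labels) ||
      ncol(mixing) != n_harmonics) {
    stop("mixing must be a channels x harmonics matrix matching the config")
  }
  if (any(mixing < 0)) stop("harmonic amplitudes must be >= 0")
  fmax <- max(vapply(class_table, `[[`, numeric(1), "frequency_hz"))
  if (rate <= 2 * n_harmonics * fmax) {
    stop("rate must exceed twice the highest harmonic frequency (",
         n_harmonics * fmax, " Hz)")
  }
  structure(list(class_table = class_table, n_harmonics = n_harmonics,
                 channel_labels = channel_labels, mixing = mixing,
                 noise_rms_uV = noise_rms_uV,
                 one_over_f_exponent = one_over_f_exponent,
                 alpha = alpha, rate = rate, trial_s = trial_s,
                 n_blocks = n_blocks, seed = seed),
            class = "ssvep_sim_config")
}

# 1/f^alpha noise by spectral shaping of white noise; rms-normalized.
one_over_f_noise <- function(n, rate, exponent = 1, rms = 1) {
  if (rms <= 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * rate / n
  shape <- c(0, f[-1]^(-exponent / 2))      # zero out DC
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x * rms / sd(x)
}

ssvep_waveform <- function(spec, n_harmonics, mixing, rate, n_samp) {
  t <- (seq_len(n_samp) - 1) / rate
  src <- vapply(seq_len(n_harmonics), function(h) {
    sin(2 * pi * h * spec$frequency_hz * t + h * spec$phase_rad)
  }, numeric(n_samp))                        # samples x harmonics
  mixing %*% t(src)                          # channels x samples
}

#' Simulate a blocked multi-class SSVEP session
#'
#' Each trial of class `f` is the sum over harmonics `h` of
#' `A[c,h] * sin(2 pi h f t + h phi)` on every channel `c`, plus 1/f noise
#' and, when enabled, an alpha-band component. Trial order is randomized
#' within each block; block indices are recorded for leave-one-block-out
#' cross-validation.
#'
#' @param cfg an [ssvep_sim_config()].
#' @return a [trial_set()] with `n_blocks * n_classes` trials.
#' @export
simulate_ssvep_trials <- function(cfg) {
  stopifnot(inherits(cfg, "ssvep_sim_config"))
  n_cls <- length(cfg$class_table)
  n_ch <- length(cfg$channel_labels)
  n_samp <- round(cfg$trial_s * cfg$rate)
  n_tr <- cfg$n_blocks * n_cls
  earbci_log("simulate_ssvep_trials: ", n_cls, " classes x ", cfg$n_blocks,
             " blocks, ", n_ch, " ch, ", n_samp, " samples @ ", cfg$rate, " Hz")
  clean <- lapply(cfg$class_table, ssvep_waveform, n_harmonics = cfg$n_harmonics,
                  mixing = cfg$mixing, rate = cfg$rate, n_samp = n_samp)
  withr::with_seed(cfg$seed, {
    dat <- array(0, dim = c(n_tr, n_ch, n_samp))
    labels <- integer(n_tr)
    blocks <- integer(n_tr)
    i <- 0L
    for (b in seq_len(cfg$n_blocks)) {
      for (cls in sample.int(n_cls)) {
        i <- i + 1L
        ep <- clean[[cls]]
        if (cfg$noise_rms_uV > 0) {
          for (c in seq_len(n_ch)) {
            ep[c, ] <- ep[c, ] + one_over_f_noise(n_samp, cfg$rate,
                                                  cfg$one_over_f_exponent,
                                                  cfg$noise_rms_uV)
          }
        }
        if (isTRUE(cfg$alpha$on) && cfg$alpha$rms_uV > 0) {
          ab <- alpha_burst(n_samp, cfg$rate, cfg$alpha$center_hz,
                            cfg$alpha$rms_uV)
          ep <- ep + matrix(ab, n_ch, n_samp, byrow = TRUE)
        }
        dat[i, , ] <- ep
        labels[i] <- cls
        blocks[i] <- b
      }
    }
    trial_set(dat, cfg$rate, labels, cfg$class_table, cfg$channel_labels,
              blocks = blocks)
  })
}

# band-limited amplitude-modulated oscillation centred at center_hz
alpha_burst <- function(n_samp, rate, center_hz, rms) {
  x <- rnorm(n_samp)
  lo <- max(0.5, center_hz - 1)
  hi <- min(rate / 2 - 1, center_hz + 1)
  y <- bp_matrix(matrix(x, 1), rate, lo, hi, order = 2)[1, ]
  y * rms / sd(y)
}

#' Simulate eyes-closed resting EEG with an alpha rhythm
#'
#' Band-limited noise centred at the configured alpha frequency (its
#' narrow-band nature produces the characteristic waxing-and-waning
#' amplitude modulation) superimposed on 1/f background noise.
#'
#' @param cfg an [ssvep_sim_config()] with `alpha$on = TRUE`.
#' @param duration_s length of the recording in seconds.
#' @return an [recording()].
#' @export
simulate_alpha_rest <- function(cfg, duration_s) {
  stopifnot(inherits(cfg, "ssvep_sim_config"), duration_s > 0)
  if (!isTRUE(cfg$alpha$on)) stop("simulate_alpha_rest requires alpha$on = TRUE")
  n_samp <- round(duration_s * cfg$rate)
  n_ch <- length(cfg$channel_labels)
  withr::with_seed(cfg$seed, {
    dat <- matrix(0, n_ch, n_samp)
    for (c in seq_len(n_ch)) {
      x <- one_over_f_noise(n_samp, cfg$rate, cfg$one_over_f_exponent,
                            max(cfg$noise_rms_uV, 1e-12))
      if (cfg$alpha$rms_uV > 0) {
        x <- x + alpha_burst(n_samp, cfg$rate, cfg$alpha$center_hz,
                             cfg$alpha$rms_uV)
      }
      dat[c, ] <- x
    }
    recording(dat, cfg$rate, cfg$channel_labels)
  })
}

#' Ground-truth temporal response function
#'
#' A TRF built as a sum of Gaussian bumps (width 15 ms) at the given lags
#' and amplitudes, sampled on the lag grid `lag_range_ms` at `1/rate`
#' steps, optionally scaled per channel.
#'
#' @param peak_lags_ms lag of each bump in milliseconds.
#' @param peak_amps amplitude of each bump (microvolts per unit stimulus).
#' @param lag_range_ms length-2 lag window, e.g. `c(0, 500)`.
#' @param n_channels number of channels.
#' @param rate sampling rate in Hz.
#' @param channel_gains optional per-channel multiplier (default a fixed
#'   0.8--1.2 ramp).
#' @param width_ms Gaussian bump width (SD) in milliseconds.
#' @return object of class `trf_model` with `weights` (lag x channel),
#'   `lag_range_ms`, `lags_ms`, `rate`.
#' @export
make_ground_truth_trf <- function(peak_lags_ms, peak_amps, lag_range_ms,
                                  n_channels, rate, channel_gains = NULL,
                                  width_ms = 15) {
  stopifnot(length(peak_lags_ms) == length(peak_amps), n_channels >= 1)
  if (any(peak_lags_ms < lag_range_ms[1] | peak_lags_ms > lag_range_ms[2])) {
    stop("every peak lag must lie inside lag_range_ms")
  }
  lags_ms <- seq(lag_range_ms[1], lag_range_ms[2], by = 1000 / rate)
  kern <- rep(0, length(lags_ms))
  for (k in seq_along(peak_lags_ms)) {
    kern <- kern + peak_amps[k] * exp(-((lags_ms - peak_lags_ms[k])^2) /
                                        (2 * width_ms^2))
  }
  if (is.null(channel_gains)) {
    channel_gains <- 0.8 + 0.4 * (seq_len(n_channels) - 1) /
      max(1, n_channels - 1)
  }
  stopifnot(length(channel_gains) == n_channels)
  w <- outer(kern, channel_gains)
  structure(list(weights = w, lag_range_ms = lag_range_ms, lags_ms = lags_ms,
                 rate = rate, lambda = NA_real_, residual_rms = NULL),
            class = "trf_model")
}

#' Cocktail-party simulation configuration
#'
#' Two-speaker trials: the EEG is the sum of a ground-truth attended TRF
#' convolved with the attended speaker's onset envelope, an ignored TRF
#' convolved with the other stream, and pink noise. Defaults follow the
#' study conditions: 60 s trials at 128 Hz, syllabic onset pulses around
#' 4 Hz, 24 trials, 10 in-ear channels; the attended TRF has peaks at
#' 80 ms (+1.2 uV) and 160 ms (-0.8 uV), the ignored TRF is the attended
#' one scaled by `ignored_scale` (default 1/3, top-down attenuation of the
#' unattended stream), and the noise RMS is 0.3 uV ("high SNR").
#'
#' @param trial_s trial length in seconds (default 60).
#' @param env_rate envelope/EEG rate in Hz (default 128).
#' @param pulse_rate_hz mean onset-pulse rate (default 4, syllabic).
#' @param trf_attended,trf_ignored ground-truth [make_ground_truth_trf()]
#'   objects; defaults built from `peak_lags_ms`/`peak_amps`/`ignored_scale`.
#' @param peak_lags_ms,peak_amps attended-TRF peaks used when
#'   `trf_attended` is `NULL`.
#' @param ignored_scale ignored/attended amplitude ratio (default 1/3).
#' @param lag_range_ms TRF lag support (default `c(0, 400)`).
#' @param noise_rms_uV additive pink-noise RMS per channel.
#' @param n_trials number of trials (default 24).
#' @param n_channels number of channels (default 10).
#' @param seed RNG seed.
#' @return validated list of class `cocktail_sim_config`.
#' @export
cocktail_sim_config <- function(trial_s = 60, env_rate = 128,
                                pulse_rate_hz = 4,
                                trf_attended = NULL, trf_ignored = NULL,
                                peak_lags_ms = c(80, 160),
                                peak_amps = c(1.2, -0.8),
                                ignored_scale = 1 / 3,
                                lag_range_ms = c(0, 400),
                                noise_rms_uV = 0.3,
                                n_trials = 24, n_channels = 10, seed = 1) {
  stopifnot(trial_s > 0, env_rate > 0, n_trials >= 1, n_channels >= 1,
            noise_rms_uV >= 0)
  if (pulse_rate_hz >= env_rate / 2) {
    stop("pulse_rate_hz must be below env_rate/2")
  }
  if (is.null(trf_attended)) {
    trf_attended <- make_ground_truth_trf(peak_lags_ms, peak_amps,
                                          lag_range_ms, n_channels, env_rate)
  }
  if (is.null(trf_ignored)) {
    trf_ignored <- make_ground_truth_trf(peak_lags_ms,
                                         peak_amps * ignored_scale,
                                         lag_range_ms, n_channels, env_rate)
  }
  if (!identical(trf_attended$lag_range_ms, trf_ignored$lag_range_ms)) {
    stop("attended and ignored TRFs must share the same lag range")
  }
  if (ncol(trf_attended$weights) != n_channels ||
      ncol(trf_ignored$weights) != n_channels) {
    stop("TRF channel count must match n_channels")
  }
  structure(list(trial_s = trial_s, env_rate = env_rate,
                 pulse_rate_hz = pulse_rate_hz,
                 trf_attended = trf_attended, trf_ignored = trf_ignored,
                 noise_rms_uV = noise_rms_uV, n_trials = n_trials,
                 n_channels = n_channels, seed = seed),
            class = "cocktail_sim_config")
}

#' Simulate a speech onset envelope
#'
#' A sparse nonnegative pulse train: pulse times follow a Poisson process
#' at `pulse_rate_hz` with a 100 ms refractory period (syllable-like
#' spacing), pulse heights are jittered, and the train is smoothed with a
#' short Hann kernel and peak-normalized to 1.
#'
#' @param cfg a [cocktail_sim_config()].
#' @param seed optional RNG seed overriding `cfg$seed`.
#' @return an [envelope()] of length `trial_s * env_rate`.
#' @export
simulate_onset_envelope <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cocktail_sim_config"))
  n <- round(cfg$trial_s * cfg$env_rate)
  if (cfg$pulse_rate_hz <= 0) return(envelope(numeric(n), cfg$env_rate))
  refr <- 0.1                                    # 100 ms refractory
  if (cfg$pulse_rate_hz >= 1 / refr) {
    stop("pulse_rate_hz must be below 1/refractory = ", 1 / refr, " Hz")
  }
  withr::with_seed(if (is.null(seed)) cfg$seed else seed, {
    # exponential rate chosen so the mean inter-pulse interval including the
    # refractory period is 1/pulse_rate_hz
    exp_rate <- 1 / (1 / cfg$pulse_rate_hz - refr)
    t <- 0
    pulses <- numeric(0)
    repeat {
      t <- t + refr + stats::rexp(1, exp_rate)
      if (t >= cfg$trial_s) break
      pulses <- c(pulses, t)
    }
    x <- numeric(n)
    idx <- pmin(n, 1L + round(pulses * cfg$env_rate))
    x[idx] <- 0.5 + runif(length(idx))
    klen <- max(3L, round(0.05 * cfg$env_rate))  # 50 ms Hann smoother
    k <- 0.5 - 0.5 * cos(2 * pi * seq_len(klen) / (klen + 1))
    y <- stats::convolve(x, rev(k), type = "open")
    y <- y[seq_len(n) + floor(klen / 2)]
    if (max(y) > 0) y <- y / max(y)
    envelope(pmax(y, 0), cfg$env_rate)
  })
}

# causal convolution of a stimulus with a lag x channel kernel:
# out[t, c] = sum_tau w[tau, c] * s[t - tau + 1]
conv_trf <- function(trf, env_values) {
  n <- length(env_values)
  n_lag <- nrow(trf$weights)
  out <- matrix(0, ncol(trf$weights), n)
  lag0 <- round(trf$lag_range_ms[1] * trf$rate / 1000)
  for (c in seq_len(ncol(trf$weights))) {
    full <- stats::convolve(env_values, rev(trf$weights[, c]), type = "open")
    out[c, ] <- full[seq_len(n)]
  }
  if (lag0 > 0) {                      # shift for a nonzero minimum lag
    out <- cbind(matrix(0, nrow(out), lag0), out[, seq_len(n - lag0), drop = FALSE])
  }
  out
}

#' Simulate one two-speaker cocktail-party trial
#'
#' EEG channel `n` is `conv(trf_attended[, n], env_att) +
#' conv(trf_ignored[, n], env_ign) + noise`; which of the two streams is
#' attended is assigned pseudo-randomly per trial. The ground-truth TRFs
#' and both stream envelopes are returned for recovery tests.
#'
#' @param cfg a [cocktail_sim_config()].
#' @param trial_index index of the trial (offsets the seed so trials are
#'   independent but individually reproducible).
#' @return list with `eeg` ([recording()]), `env_streams` (list of two
#'   [envelope()]s in presentation order), `attended` (1 or 2),
#'   `env_attended`, `env_ignored`, and the ground-truth TRFs.
#' @export
simulate_cocktail_trial <- function(cfg, trial_index = 1) {
  stopifnot(inherits(cfg, "cocktail_sim_config"))
  base <- cfg$seed + 7919L * (trial_index - 1L)
  env1 <- simulate_onset_envelope(cfg, seed = base + 1L)
  env2 <- simulate_onset_envelope(cfg, seed = base + 2L)
  withr::with_seed(base + 3L, {
    attended <- sample(1:2, 1)
    env_att <- if (attended == 1) env1 else env2
    env_ign <- if (attended == 1) env2 else env1
    x <- conv_trf(cfg$trf_attended, env_att$values) +
      conv_trf(cfg$trf_ignored, env_ign$values)
    if (cfg$noise_rms_uV > 0) {
      for (c in seq_len(nrow(x))) {
        x[c, ] <- x[c, ] + one_over_f_noise(ncol(x), cfg$env_rate, 1,
                                            cfg$noise_rms_uV)
      }
    }
    labs <- if (cfg$n_channels == 10) {
      c(paste0("L", 1:5), paste0("R", 1:5))
    } else {
      paste0("ch", seq_len(cfg$n_channels))
    }
    list(eeg = recording(x, cfg$env_rate, labs),
         env_streams = list(env1, env2), attended = attended,
         env_attended = env_att, env_ignored = env_ign,
         trf_attended = cfg$trf_attended, trf_ignored = cfg$trf_ignored)
  })
}

#' Simulate a full cocktail-party session
#'
#' @param cfg a [cocktail_sim_config()].
#' @return list of `cfg$n_trials` trials from [simulate_cocktail_trial()].
#' @export
simulate_cocktail_trials <- function(cfg) {
  earbci_log("simulate_cocktail_trials: ", cfg$n_trials, " trials of ",
             cfg$trial_s, " s @ ", cfg$env_rate, " Hz")
  lapply(seq_len(cfg$n_trials), function(i) simulate_cocktail_trial(cfg, i))
}
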
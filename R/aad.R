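# Auditory attention decoding. The linear model is
#   x(t, n) = sum_tau w(tau, n) s(t - tau) + eps(t, n)
# estimated forward (TRF: stimulus -> EEG, per channel) and backward
# (decoder: lagged multichannel EEG -> stimulus) by ridge regression.
# Attention is classified by comparing the correlation of the
# decoder-reconstructed stimulus with each candidate stream's envelope.

ms_to_samples <- function(ms, rate) round(ms * rate / 1000)

#' ERB-spaced auditory filterbank centre frequencies
#'
#' Centres uniformly spaced on the ERB-number scale between `f_lo` and
#' `f_hi` (defaults 180--7246 Hz, 128 bands, the speech range used for
#' envelope extraction).
#'
#' @param f_lo,f_hi frequency range in Hz.
#' @param n number of bands.
#' @return numeric vector of centre frequencies.
#' @export
erb_space <- function(f_lo = 180, f_hi = 7246, n = 128) {
  erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
  erb_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
  erb_inv(seq(erb(f_lo), erb(f_hi), length.out = n))
}

#' Auditory spectrogram of a speech waveform
#'
#' Decomposes the waveform with a bank of band-pass filters (2nd-order
#' Butterworth, one equivalent rectangular bandwidth wide) at ERB-spaced
#' centres, squares each band signal, smooths it with a low-pass at half
#' the envelope rate and decimates to `env_rate`. The result is the
#' band x time sub-band power matrix whose column sum is the broadband
#' envelope.
#'
#' @param waveform numeric audio samples (mono).
#' @param audio_rate audio sampling rate in Hz; must be at least twice the
#'   top band edge.
#' @param n_bands,f_lo,f_hi filterbank layout (defaults 128 bands,
#'   180--7246 Hz).
#' @param env_rate output frame rate in Hz (default 128).
#' @return list of class `aud_spectrogram` with `power` (band x frame),
#'   `center_hz`, `rate` (frame rate).
#' @export
audio_to_spectrogram <- function(waveform, audio_rate, n_bands = 128,
                                 f_lo = 180, f_hi = 7246, env_rate = 128) {
  if (audio_rate < 2 * f_hi) {
    stop("audio_rate ", audio_rate, " Hz is below twice the top band edge (",
         2 * f_hi, " Hz)")
  }
  centers <- erb_space(f_lo, f_hi, n_bands)
  nyq <- audio_rate / 2
  n_frames <- max(1L, floor(length(waveform) * env_rate / audio_rate))
  power <- matrix(0, n_bands, n_frames)
  if (all(waveform == 0)) {
    return(structure(list(power = power, center_hz = centers,
                          rate = env_rate), class = "aud_spectrogram"))
  }
  lp <- signal::butter(4, min(0.99, (env_rate / 2) / nyq), type = "low")
  frac <- .ratio(env_rate / audio_rate)
  for (b in seq_len(n_bands)) {
    bw <- 24.7 * (4.37 * centers[b] / 1000 + 1)       # 1 ERB bandwidth
    lo <- max(centers[b] - bw / 2, 1) / nyq
    hi <- min(centers[b] + bw / 2, nyq * 0.999) / nyq
    bpf <- signal::butter(2, c(lo, hi), type = "pass")
    y <- signal::filtfilt(bpf, waveform)
    p <- signal::filtfilt(lp, y^2)                    # smoothed band power
    z <- signal::resample(p, frac[1], frac[2])
    power[b, ] <- pmax(z[seq_len(n_frames)], 0)
  }
  structure(list(power = power, center_hz = centers, rate = env_rate),
            class = "aud_spectrogram")
}

#' Onset envelope of a speech stimulus
#'
#' Sums the auditory spectrogram across bands to the broadband envelope and
#' takes its half-wave-rectified first difference — a nonnegative measure
#' of salient power increases (acoustic onsets) used as the stimulus
#' feature `s(t)` for TRF modeling.
#'
#' @param x an `aud_spectrogram` from [audio_to_spectrogram()], or a raw
#'   waveform (then `audio_rate` is required and a spectrogram is computed
#'   first).
#' @param audio_rate audio rate in Hz for waveform input.
#' @param ... passed to [audio_to_spectrogram()] for waveform input.
#' @return an [envelope()] at the spectrogram frame rate.
#' @export
extract_onset_envelope <- function(x, audio_rate = NULL, ...) {
  if (!inherits(x, "aud_spectrogram")) {
    if (is.null(audio_rate)) stop("waveform input requires `audio_rate`")
    x <- audio_to_spectrogram(x, audio_rate, ...)
  }
  broadband <- colSums(x$power)
  onset <- pmax(c(0, diff(broadband)), 0)
  envelope(onset, x$rate)
}

# lagged design matrix of a single series: row t holds s[t - tau] for
# tau = lag_min..lag_max (samples); only fully valid rows are kept.
lagged_design <- function(s, lag_min, lag_max) {
  n <- length(s)
  lags <- lag_min:lag_max
  valid <- (1 + max(lag_max, 0)):(n + min(lag_min, 0))
  S <- vapply(lags, function(tau) s[valid - tau], numeric(length(valid)))
  list(S = S, rows = valid, lags = lags)
}

#' Fit a forward temporal response function
#'
#' Per-channel ridge regression of the EEG on the lagged stimulus: with
#' design `S` holding `s(t - tau)` for lags spanning `lag_range_ms`
#' (default 0--500 ms), the weights solve
#' `w = (S'S + lambda I)^-1 S' x_n`; `lambda = 0` reproduces ordinary
#' least squares. Edge samples inside the lag span are trimmed from the
#' design rather than zero-padded.
#'
#' @param s an [envelope()] (or numeric vector at the EEG rate).
#' @param x an [recording()] at the same rate and duration.
#' @param lag_range_ms length-2 lag window in milliseconds.
#' @param lambda ridge penalty (default 0).
#' @return a `trf_model` with `weights` (lag x channel), `lags_ms`,
#'   `lambda` and per-channel `residual_rms`.
#' @export
fit_forward_trf <- function(s, x, lag_range_ms = c(0, 500), lambda = 0) {
  stopifnot(inherits(x, "eeg_recording"))
  sv <- if (inherits(s, "envelope")) s$values else as.numeric(s)
  if (inherits(s, "envelope") && abs(s$rate - x$rate) > 1e-9) {
    stop("stimulus and EEG rates differ")
  }
  if (length(sv) != ncol(x$data)) stop("stimulus and EEG durations differ")
  if (all(sv == 0)) stop("degenerate design: stimulus is identically zero")
  l0 <- ms_to_samples(lag_range_ms[1], x$rate)
  l1 <- ms_to_samples(lag_range_ms[2], x$rate)
  if (l1 - l0 + 1 >= length(sv)) stop("recording shorter than the lag span")
  d <- lagged_design(sv, l0, l1)
  G <- crossprod(d$S) + diag(lambda, ncol(d$S))
  W <- solve(G, crossprod(d$S, t(x$data[, d$rows, drop = FALSE])))
  fitted <- d$S %*% W
  resid <- t(x$data[, d$rows, drop = FALSE]) - fitted
  structure(list(weights = W, lag_range_ms = lag_range_ms,
                 lags_ms = d$lags * 1000 / x$rate, rate = x$rate,
                 lambda = lambda,
                 residual_rms = apply(resid, 2, function(r) sqrt(mean(r^2)))),
            class = "trf_model")
}

# backward design: predictors x(t + tau, n) for tau = 0..lag_max over all
# channels; response s(t). Returns Gram/cross-product accumulators so
# trials can be pooled cheaply.
backward_design <- function(eeg_data, sv, lag_max) {
  n <- length(sv)
  valid <- 1:(n - lag_max)
  blocks <- lapply(0:lag_max, function(tau) {
    t(eeg_data[, valid + tau, drop = FALSE])
  })
  X <- do.call(cbind, blocks)             # rows t, cols (tau, channel)
  y <- sv[valid]
  list(XtX = crossprod(X), Xty = crossprod(X, y), X = X, y = y)
}

solve_backward <- function(XtX, Xty, lambda) {
  solve(XtX + diag(lambda * mean(diag(XtX)), nrow(XtX)), Xty)
}

#' Fit a backward (stimulus-reconstruction) decoder
#'
#' Ridge regression of the stimulus envelope on lagged multichannel EEG
#' (EEG lags 0 to `lag_range_ms[2]` after the stimulus), pooled over
#' training trials. When `lambda` is a grid, the penalty is selected by
#' inner leave-one-trial-out cross-validation maximizing the mean
#' reconstruction correlation (requires >= 2 trials). The penalty is
#' scaled by the mean diagonal of the pooled Gram matrix so the grid is
#' dimensionless.
#'
#' @param trials list of `list(eeg = recording, env = envelope)` pairs; for
#'   `kind = "attended"` the envelopes must be the attended stream, for
#'   `kind = "ignored"` the ignored one.
#' @param lag_range_ms EEG lag window in milliseconds (default 0--250; the
#'   lower edge is fixed at 0).
#' @param lambda a single relative penalty, or a grid to select from
#'   (default `c(1e-4, 1e-2, 1)`).
#' @param kind `"attended"` or `"ignored"`, recorded on the decoder.
#' @return object of class `backward_decoder` with `weights`
#'   (lag x channel), `lag_range_ms`, `lambda`, `kind`.
#' @export
fit_backward_decoder <- function(trials, lag_range_ms = c(0, 250),
                                 lambda = c(1e-4, 1e-2, 1),
                                 kind = c("attended", "ignored")) {
  kind <- match.arg(kind)
  stopifnot(length(trials) >= 1)
  n_ch <- nrow(trials[[1]]$eeg$data)
  rate <- trials[[1]]$eeg$rate
  lag_max <- ms_to_samples(lag_range_ms[2], rate)
  designs <- lapply(trials, function(tr) {
    if (nrow(tr$eeg$data) != n_ch) {
      stop("inconsistent channel counts across training trials")
    }
    sv <- if (inherits(tr$env, "envelope")) tr$env$values else tr$env
    backward_design(tr$eeg$data, sv, lag_max)
  })
  fit_backward_from_designs(designs, lag_max, rate, n_ch, lambda, kind)
}

# core backward fit from precomputed per-trial designs (allows the
# leave-one-out driver to build each trial's design exactly once)
fit_backward_from_designs <- function(designs, lag_max, rate, n_ch,
                                      lambda, kind) {
  XtX <- Reduce(`+`, lapply(designs, `[[`, "XtX"))
  Xty <- Reduce(`+`, lapply(designs, `[[`, "Xty"))
  if (length(lambda) > 1L && length(designs) >= 2L) {
    score <- vapply(lambda, function(lam) {
      r <- vapply(seq_along(designs), function(i) {
        g <- solve_backward(XtX - designs[[i]]$XtX, Xty - designs[[i]]$Xty, lam)
        safe_cor(designs[[i]]$X %*% g, designs[[i]]$y)
      }, numeric(1))
      mean(r)
    }, numeric(1))
    lam <- lambda[which.max(score)]
    earbci_log("fit_backward_decoder(", kind, "): lambda ", lam,
               " selected by inner CV (scores ",
               paste(signif(score, 3), collapse = ", "), ")")
  } else {
    lam <- lambda[1]
  }
  g <- solve_backward(XtX, Xty, lam)
  structure(list(weights = matrix(g, nrow = lag_max + 1, byrow = TRUE),
                 g = as.numeric(g), n_channels = n_ch, lag_max = lag_max,
                 lag_range_ms = c(0, lag_max * 1000 / rate), rate = rate,
                 lambda = lam, kind = kind),
            class = "backward_decoder")
}

#' Reconstruct the stimulus envelope from EEG
#'
#' Applies a backward decoder: `s_hat(t) = sum_{tau, n} g(tau, n)
#' x(t + tau, n)`. The `lag_max` trailing samples, whose design rows would
#' be incomplete, are trimmed (logged), so the output is shorter than the
#' recording by the lag span.
#'
#' @param dec a `backward_decoder`.
#' @param x an [recording()] with matching channels and rate.
#' @return an [envelope()]-like reconstruction (values may be negative).
#' @export
reconstruct_stimulus <- function(dec, x) {
  stopifnot(inherits(dec, "backward_decoder"), inherits(x, "eeg_recording"))
  if (nrow(x$data) != dec$n_channels) stop("channel count mismatch")
  if (abs(x$rate - dec$rate) > 1e-9) stop("rate mismatch")
  d <- backward_design(x$data, numeric(ncol(x$data)), dec$lag_max)
  earbci_log("reconstruct_stimulus: trimmed ", dec$lag_max,
             " edge samples (lag span)")
  envelope(as.numeric(d$X %*% dec$g), x$rate)
}

zscore <- function(v) {
  s <- sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' Classify the attended stream of one trial
#'
#' Primary rule: reconstruct the stimulus with the attended decoder and
#' predict the stream whose (z-scored, lag-span-trimmed) envelope
#' correlates best with the reconstruction. All four correlations (both
#' decoders x both envelopes) are reported for diagnostic analyses. Ties
#' predict stream A, flagged.
#'
#' @param dec_att,dec_ign fitted attended/ignored `backward_decoder`s.
#' @param x test-trial [recording()].
#' @param env_A,env_B candidate stream [envelope()]s aligned with `x`.
#' @return one-row data frame with the four correlations, `predicted`
#'   (`"A"`/`"B"`) and `tie`.
#' @export
classify_attention <- function(dec_att, dec_ign, x, env_A, env_B) {
  rec_att <- reconstruct_stimulus(dec_att, x)$values
  rec_ign <- reconstruct_stimulus(dec_ign, x)$values
  trim <- function(env) {
    v <- if (inherits(env, "envelope")) env$values else env
    v[seq_along(rec_att)]
  }
  a <- zscore(trim(env_A)); b <- zscore(trim(env_B))
  r <- c(r_att_A = safe_cor(zscore(rec_att), a),
         r_att_B = safe_cor(zscore(rec_att), b),
         r_ign_A = safe_cor(zscore(rec_ign), a),
         r_ign_B = safe_cor(zscore(rec_ign), b))
  tie <- r[["r_att_A"]] == r[["r_att_B"]]
  if (tie) earbci_log("classify_attention: tie; predicting stream A")
  data.frame(r_att_A = r[["r_att_A"]], r_att_B = r[["r_att_B"]],
             r_ign_A = r[["r_ign_A"]], r_ign_B = r[["r_ign_B"]],
             predicted = if (r[["r_att_A"]] >= r[["r_att_B"]]) "A" else "B",
             tie = tie, stringsAsFactors = FALSE)
}

#' Leave-one-out evaluation of attention decoding
#'
#' For each held-out trial, attended and ignored decoders are fitted on
#' the remaining trials (each trained on the envelope matching its role)
#' and [classify_attention()] is applied against the two presented
#' streams. Returns per-trial records, the pooled accuracy, the per-trial
#' attended-minus-ignored correlation differences (attended decoder's
#' correlation with the attended vs the ignored envelope), and a
#' two-sided one-sample t-test on those differences.
#'
#' @param trials list of trials from [simulate_cocktail_trial()] (or any
#'   list with `eeg`, `env_streams`, `attended`).
#' @param lag_range_ms backward lag window (default 0--250 ms).
#' @param lambda penalty or grid for [fit_backward_decoder()].
#' @return list of class `aad_result`: `records` (data frame), `accuracy`,
#'   `corr_diff` (vector), `t_test` (htest).
#' @export
loo_evaluate <- function(trials, lag_range_ms = c(0, 250),
                         lambda = c(1e-4, 1e-2, 1)) {
  n <- length(trials)
  if (n < 3) stop("loo_evaluate requires at least 3 trials")
  earbci_log("loo_evaluate: ", n, " trials, leave-one-out")
  rate <- trials[[1]]$eeg$rate
  n_ch <- nrow(trials[[1]]$eeg$data)
  lag_max <- ms_to_samples(lag_range_ms[2], rate)
  # build each trial's lagged design once; folds pool them by subtraction
  att_designs <- lapply(trials, function(tr) {
    backward_design(tr$eeg$data, tr$env_streams[[tr$attended]]$values, lag_max)
  })
  ign_designs <- lapply(trials, function(tr) {
    backward_design(tr$eeg$data, tr$env_streams[[3 - tr$attended]]$values,
                    lag_max)
  })
  records <- NULL
  for (i in seq_len(n)) {
    dec_att <- fit_backward_from_designs(att_designs[-i], lag_max, rate,
                                         n_ch, lambda, "attended")
    dec_ign <- fit_backward_from_designs(ign_designs[-i], lag_max, rate,
                                         n_ch, lambda, "ignored")
    tr <- trials[[i]]
    rec <- classify_attention(dec_att, dec_ign, tr$eeg,
                              tr$env_streams[[1]], tr$env_streams[[2]])
    rec$trial <- i
    rec$true <- c("A", "B")[tr$attended]
    records <- rbind(records, rec)
  }
  correct <- records$predicted == records$true
  # attended-decoder correlation with the attended minus the ignored stream
  r_att_on_att <- ifelse(records$true == "A", records$r_att_A, records$r_att_B)
  r_att_on_ign <- ifelse(records$true == "A", records$r_att_B, records$r_att_A)
  diffs <- r_att_on_att - r_att_on_ign
  structure(list(records = records, accuracy = mean(correct),
                 corr_diff = diffs,
                 t_test = t.test(diffs, alternative = "two.sided")),
            class = "aad_result")
}

#' @export
print.aad_result <- function(x, ...) {
  cat(sprintf("AAD leave-one-out: accuracy %.3f over %d trials\n",
              x$accuracy, nrow(x$records)))
  cat(sprintf("  corr diff (att - ign): mean %.4f, t-test p = %.3g\n",
              mean(x$corr_diff), x$t_test$p.value))
  invisible(x)
}
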
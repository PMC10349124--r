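test_that("the auditory filterbank localizes tones and handles silence", {
  fs <- 16000
  t <- (0:7999) / fs
  spg <- audio_to_spectrogram(sin(2 * pi * 1000 * t), fs, n_bands = 32,
                              env_rate = 64)
  expect_equal(nrow(spg$power), 32L)
  expect_true(all(spg$power >= 0))
  band_power <- rowMeans(spg$power)
  expect_equal(which.max(band_power),
               which.min(abs(spg$center_hz - 1000)))
  silent <- audio_to_spectrogram(rep(0, 8000), fs, n_bands = 32,
                                 env_rate = 64)
  expect_true(all(silent$power == 0))
  withr::with_seed(1, noise <- rnorm(8000))
  spn <- audio_to_spectrogram(noise, fs, n_bands = 32, env_rate = 64)
  expect_true(all(rowMeans(spn$power) > 0))
  expect_error(audio_to_spectrogram(noise, 8000), "twice")
})

test_that("onset envelopes are rectified derivatives of the broadband envelope", {
  fs <- 16000
  t <- (0:15999) / fs
  # constant-amplitude tone: no onsets after the initial transient
  tone <- sin(2 * pi * 1000 * t)
  env <- extract_onset_envelope(tone, fs, n_bands = 16, env_rate = 64)
  expect_true(all(env$values >= 0))
  expect_lt(max(env$values[20:64]), 0.1 * max(env$values))
  # amplitude step: one dominant onset at the step time
  stepped <- tone * c(rep(0.1, 8000), rep(1, 8000))
  env2 <- extract_onset_envelope(stepped, fs, n_bands = 16, env_rate = 64)
  expect_equal(which.max(env2$values) / 64, 0.5, tolerance = 0.05)
  # click train: one onset peak per click
  clicks <- rep(0, 16000)
  click_times <- seq(0.1, 0.9, by = 1 / 3)
  clicks[round(click_times * fs)] <- 1
  env3 <- extract_onset_envelope(clicks, fs, n_bands = 16, env_rate = 64)
  thr <- 0.3 * max(env3$values)
  peaks <- which(diff(sign(diff(env3$values))) == -2) + 1
  expect_equal(sum(env3$values[peaks] > thr), length(click_times))
})

test_that("forward TRF recovers a known kernel from noiseless data", {
  rate <- 64
  withr::with_seed(20, s <- rnorm(rate * 30))       # white stimulus
  # 375 ms spans an integer number of 1/64 s lag steps, aligning the
  # ground-truth grid with the estimator's
  w_true <- make_ground_truth_trf(c(80, 200), c(1, -0.5), c(0, 375),
                                  n_channels = 3, rate = rate)
  n <- length(s)
  out <- matrix(0, 3, n)
  for (c in 1:3) {
    full <- stats::convolve(s, rev(w_true$weights[, c]), type = "open")
    out[c, ] <- full[seq_len(n)]
  }
  eeg <- recording(out, rate)
  m <- fit_forward_trf(s, eeg, lag_range_ms = c(0, 375), lambda = 0)
  for (c in 1:3) {
    expect_gt(cor(m$weights[, c], w_true$weights[, c]), 0.999)
  }
  expect_lt(max(m$residual_rms), 1e-6)
  expect_error(fit_forward_trf(rep(0, rate * 30), eeg), "degenerate")
  short <- recording(matrix(rnorm(3 * 20), 3), rate)
  expect_error(fit_forward_trf(rnorm(20), short, c(0, 400)), "lag span")
})

test_that("ridge shrinks the forward TRF monotonically", {
  rate <- 64
  withr::with_seed(21, {
    s <- rnorm(rate * 10)
    eeg <- recording(matrix(rnorm(2 * rate * 10), 2), rate)
  })
  norms <- vapply(c(0, 1, 100, 1e4, 1e6), function(lam) {
    sqrt(sum(fit_forward_trf(s, eeg, c(0, 200), lam)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("ridge solutions equal a brute-force normal-equations oracle", {
  rate <- 32
  withr::with_seed(22, {
    s <- rnorm(200)
    x <- matrix(rnorm(3 * 200), 3)
  })
  eeg <- recording(x, rate)
  lags <- 0:4
  for (lam in c(0, 0.5, 10)) {
    m <- fit_forward_trf(s, eeg, lag_range_ms = c(0, 4000 / 32), lambda = lam)
    for (c in 1:3) {
      w_oracle <- oracle_ridge_trf(s, x[c, ], lags, lam)
      expect_equal(m$weights[, c], as.numeric(w_oracle), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("backward decoding reconstructs the stimulus it was trained on", {
  # a single-bump kernel keeps the deconvolution well conditioned, so the
  # self-consistency property is visible undiluted
  cfg <- small_cocktail_cfg(noise_rms_uV = 0, ignored_scale = 0,
                            trial_s = 20, peak_lags_ms = 80, peak_amps = 1.2)
  tr <- simulate_cocktail_trial(cfg, 1)
  dec <- fit_backward_decoder(list(list(eeg = tr$eeg, env = tr$env_attended)),
                              lambda = 1e-6, kind = "attended")
  expect_identical(dec$kind, "attended")
  rec <- reconstruct_stimulus(dec, tr$eeg)
  n <- length(rec$values)
  expect_gt(cor(rec$values, tr$env_attended$values[seq_len(n)]), 0.95)
  # lambda grid of one value is the fixed-lambda fit
  dec2 <- fit_backward_decoder(list(list(eeg = tr$eeg, env = tr$env_attended)),
                               lambda = c(1e-6), kind = "ignored")
  expect_equal(dec2$g, dec$g)
  expect_identical(dec2$kind, "ignored")
})

test_that("reconstruction is linear and zero for zero input", {
  cfg <- small_cocktail_cfg()
  tr <- simulate_cocktail_trial(cfg, 1)
  dec <- fit_backward_decoder(list(list(eeg = tr$eeg, env = tr$env_attended)),
                              lambda = 1e-2, kind = "attended")
  zero <- recording(matrix(0, 4, 640), 64)
  expect_true(all(reconstruct_stimulus(dec, zero)$values == 0))
  r1 <- reconstruct_stimulus(dec, tr$eeg)$values
  tr2 <- tr$eeg; tr2$data <- 2.5 * tr2$data
  expect_equal(reconstruct_stimulus(dec, tr2)$values, 2.5 * r1,
               tolerance = 1e-12)
  expect_error(reconstruct_stimulus(dec, recording(matrix(0, 2, 640), 64)),
               "channel")
})

test_that("attention classification follows the stronger correlation and flags ties", {
  cfg <- small_cocktail_cfg(trial_s = 20, seed = 2)
  trials <- simulate_cocktail_trials(cfg)
  att_tr <- lapply(trials[-1], function(tr) {
    list(eeg = tr$eeg, env = tr$env_streams[[tr$attended]])
  })
  ign_tr <- lapply(trials[-1], function(tr) {
    list(eeg = tr$eeg, env = tr$env_streams[[3 - tr$attended]])
  })
  dec_att <- fit_backward_decoder(att_tr, lambda = 1e-2, kind = "attended")
  dec_ign <- fit_backward_decoder(ign_tr, lambda = 1e-2, kind = "ignored")
  tr <- trials[[1]]
  rec <- classify_attention(dec_att, dec_ign, tr$eeg,
                            tr$env_streams[[1]], tr$env_streams[[2]])
  expect_identical(rec$predicted, c("A", "B")[tr$attended])
  # swapping the candidate envelopes inverts the decision
  swapped <- classify_attention(dec_att, dec_ign, tr$eeg,
                                tr$env_streams[[2]], tr$env_streams[[1]])
  expect_identical(swapped$predicted, c("A", "B")[3 - tr$attended])
  # identical candidates tie and resolve to A
  same <- classify_attention(dec_att, dec_ign, tr$eeg,
                             tr$env_streams[[1]], tr$env_streams[[1]])
  expect_true(same$tie)
  expect_identical(same$predicted, "A")
})

test_that("leave-one-out evaluation yields one record per trial", {
  cfg <- small_cocktail_cfg(seed = 3)
  trials <- simulate_cocktail_trials(cfg)
  res <- loo_evaluate(trials, lambda = 1e-2)
  expect_equal(nrow(res$records), length(trials))
  expect_true(all(res$records$predicted %in% c("A", "B")))
  expect_length(res$corr_diff, length(trials))
  expect_s3_class(res$t_test, "htest")
  expect_error(loo_evaluate(trials[1:2]), "at least 3")
})

test_that("forward then backward modeling round-trips a noiseless stream", {
  cfg <- small_cocktail_cfg(noise_rms_uV = 0, ignored_scale = 0,
                            trial_s = 20, seed = 4,
                            peak_lags_ms = 80, peak_amps = 1.2)
  tr <- simulate_cocktail_trial(cfg, 1)
  fwd <- fit_forward_trf(tr$env_attended, tr$eeg, c(0, 400), lambda = 1e-8)
  # re-simulate EEG from the estimated forward model, then decode backward
  n <- length(tr$env_attended$values)
  sim <- matrix(0, 4, n)
  for (c in 1:4) {
    full <- stats::convolve(tr$env_attended$values, rev(fwd$weights[, c]),
                            type = "open")
    sim[c, ] <- full[seq_len(n)]
  }
  dec <- fit_backward_decoder(list(list(eeg = recording(sim, 64),
                                        env = tr$env_attended)),
                              lambda = 1e-6, kind = "attended")
  rec <- reconstruct_stimulus(dec, recording(sim, 64))
  expect_gt(cor(rec$values,
                tr$env_attended$values[seq_along(rec$values)]), 0.95)
})

test_that("TRF estimates are accurate at low noise over repeated simulations", {
  cors <- vapply(1:10, function(s) {
    cfg <- small_cocktail_cfg(noise_rms_uV = 0, ignored_scale = 0,
                              trial_s = 20, seed = s)
    tr <- simulate_cocktail_trial(cfg, 1)
    sig_rms <- sqrt(mean(tr$eeg$data^2))
    noisy <- tr$eeg
    withr::with_seed(1000 + s, {
      noisy$data <- noisy$data + matrix(rnorm(length(noisy$data),
                                              sd = 0.2 * sig_rms),
                                        nrow(noisy$data))
    })
    # the onset envelope is autocorrelated, so a modest ridge stabilizes
    # the estimate without biasing the bump locations
    m <- fit_forward_trf(tr$env_attended, noisy, c(0, 400), lambda = 1)
    k <- nrow(cfg$trf_attended$weights)
    mean(vapply(1:4, function(c) cor(m$weights[seq_len(k), c],
                                     cfg$trf_attended$weights[, c]),
                numeric(1)))
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})

test_that("attention decoding accuracy does not increase with noise", {
  acc <- vapply(c(0.05, 0.6, 6), function(noise) {
    mean(vapply(1:6, function(s) {
      cfg <- small_cocktail_cfg(noise_rms_uV = noise, seed = s)
      loo_evaluate(simulate_cocktail_trials(cfg), lambda = 1e-2)$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.05),
              info = paste(round(acc, 3), collapse = " "))
})
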
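test_that("noiseless SSVEP trials put energy only at programmed harmonics", {
  cfg <- ssvep_sim_config(class_table = list(stimulus_spec(10, 0, 4)),
                          noise_rms_uV = 0, n_blocks = 1, trial_s = 4)
  ts <- simulate_ssvep_trials(cfg)
  expect_equal(dim(ts$data), c(1L, 10L, 1000L))
  for (c in c(1, 5, 10)) {
    sp <- psd(ts$data[1, c, ], cfg$rate)
    harm <- sp$freq %in% c(10, 20, 30)
    expect_lt(sum(sp$F[!harm]), 1e-18 * sum(sp$F))
    expect_gt(min(sp$F[harm]), 0)
  }
})

test_that("simulators are bit-deterministic given config and seed", {
  cfg <- ssvep_sim_config(seed = 11, n_blocks = 2, trial_s = 1)
  expect_identical(simulate_ssvep_trials(cfg), simulate_ssvep_trials(cfg))
  cfg2 <- ssvep_sim_config(seed = 12, n_blocks = 2, trial_s = 1)
  expect_false(identical(simulate_ssvep_trials(cfg)$data,
                         simulate_ssvep_trials(cfg2)$data))
  ccfg <- small_cocktail_cfg(seed = 5)
  expect_identical(simulate_cocktail_trial(ccfg, 2),
                   simulate_cocktail_trial(ccfg, 2))
  expect_identical(simulate_onset_envelope(ccfg),
                   simulate_onset_envelope(ccfg))
})

test_that("simulated trials carry narrow-band SNR at their own frequency", {
  cfg <- ssvep_sim_config(seed = 1, trial_s = 4, n_blocks = 1)
  ts <- simulate_ssvep_trials(cfg)
  off_freqs <- c(8.7, 9.3, 10.7, 11.3)         # no class, no harmonic
  for (i in seq_len(n_trials(ts))) {
    f0 <- ts$stimuli[[ts$labels[i]]]$frequency_hz
    sp <- psd(ts$data[i, , ], ts$rate)
    snr_f0 <- mean(narrowband_snr(sp, f0, K = 4))
    snr_off <- mean(vapply(off_freqs,
                           function(f) mean(narrowband_snr(sp, f, K = 4)),
                           numeric(1)))
    expect_gt(snr_f0, snr_off)
  }
})

test_that("resting-state simulation shows an alpha peak only when enabled", {
  cfg <- ssvep_sim_config(alpha = list(center_hz = 10, rms_uV = 2, on = TRUE),
                          seed = 3)
  rec <- simulate_alpha_rest(cfg, duration_s = 60)
  expect_equal(ncol(rec$data), 15000L)
  sp <- psd(rec$data[1, ], cfg$rate)
  band <- sp$freq >= 2 & sp$freq <= 40
  peak <- sp$freq[band][which.max(sp$F[band])]
  expect_lte(abs(peak - 10), 0.5)
  # with alpha silenced there is no 10 Hz peak above the 1/f trend
  cfg0 <- ssvep_sim_config(alpha = list(center_hz = 10, rms_uV = 0, on = TRUE),
                           seed = 3)
  sp0 <- psd(simulate_alpha_rest(cfg0, 60)$data[1, ], cfg0$rate)
  at10 <- mean(sp0$F[abs(sp0$freq - 10) <= 0.5])
  trend <- mean(sp0$F[abs(sp0$freq - 10) > 1 & abs(sp0$freq - 10) < 3])
  expect_lt(at10, 2 * trend)
  expect_error(simulate_alpha_rest(ssvep_sim_config(), 10), "alpha")
})

test_that("onset envelopes are nonnegative sparse pulse trains at the set rate", {
  cfg <- cocktail_sim_config(seed = 9)
  env <- simulate_onset_envelope(cfg)
  expect_length(env$values, 60 * 128)
  expect_true(all(env$values >= 0))
  expect_equal(max(env$values), 1)
  # pulse count within the 99% Poisson interval of pulse_rate * trial_s
  peaks <- which(diff(sign(diff(env$values))) == -2) + 1
  n_pulses <- sum(env$values[peaks] > 0.1)
  expect_gte(n_pulses, qpois(0.005, cfg$pulse_rate_hz * cfg$trial_s))
  expect_lte(n_pulses, qpois(0.995, cfg$pulse_rate_hz * cfg$trial_s))
  # zero rate gives silence
  cfg0 <- cocktail_sim_config(pulse_rate_hz = 0)
  expect_true(all(simulate_onset_envelope(cfg0)$values == 0))
  expect_error(cocktail_sim_config(pulse_rate_hz = 80), "env_rate/2")
})

test_that("noiseless cocktail EEG equals the brute-force convolution", {
  cfg <- small_cocktail_cfg(noise_rms_uV = 0, ignored_scale = 0)
  tr <- simulate_cocktail_trial(cfg, 1)
  expect_equal(ncol(tr$eeg$data), 10 * 64)
  s <- tr$env_attended$values
  w <- cfg$trf_attended$weights
  n <- length(s)
  for (ch in c(1, 4)) {
    direct <- vapply(seq_len(n), function(t) {
      taus <- 0:(nrow(w) - 1)
      ok <- t - taus >= 1
      sum(w[which(ok), ch] * s[t - taus[ok]])
    }, numeric(1))
    expect_equal(tr$eeg$data[ch, ], direct, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("noiseless cocktail EEG is linear in the TRF amplitudes", {
  cfg1 <- small_cocktail_cfg(noise_rms_uV = 0)
  cfg2 <- small_cocktail_cfg(noise_rms_uV = 0,
                             peak_amps = 2 * c(1.2, -0.8))
  t1 <- simulate_cocktail_trial(cfg1, 1)
  t2 <- simulate_cocktail_trial(cfg2, 1)
  expect_equal(t2$eeg$data, 2 * t1$eeg$data, tolerance = 1e-12)
})

test_that("ground-truth TRFs are Gaussian bumps on the lag grid", {
  trf <- make_ground_truth_trf(100, 1, c(0, 500), n_channels = 3, rate = 128)
  expect_equal(nrow(trf$weights), length(seq(0, 500, by = 1000 / 128)))
  expect_equal(trf$lags_ms[which.max(trf$weights[, 1])], 101.5625,
               tolerance = 1e-6)              # lag bin nearest 100 ms
  zero <- make_ground_truth_trf(c(50, 100), c(0, 0), c(0, 300), 2, 128)
  expect_true(all(zero$weights == 0))
  expect_error(make_ground_truth_trf(600, 1, c(0, 500), 2, 128), "inside")
})

test_that("identical kernels make the two streams statistically exchangeable", {
  # with trf_ignored == trf_attended the attended-vs-ignored contrast of any
  # linear statistic has zero expectation; check the seed-averaged broadband
  # correlation contrast
  diffs <- vapply(1:10, function(s) {
    cfg <- small_cocktail_cfg(ignored_scale = 1, noise_rms_uV = 0.1, seed = s)
    tr <- simulate_cocktail_trial(cfg, 1)
    agg <- colSums(tr$eeg$data)
    cor(agg, tr$env_attended$values) - cor(agg, tr$env_ignored$values)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})
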
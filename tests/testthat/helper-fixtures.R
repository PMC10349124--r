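# Shared fixtures and independent oracles. Oracles are deliberately written
# as direct, brute-force translations of the definitions so they stay
# independent of the package's implementation paths.

# recording holding pure sinusoids (one per channel)
sine_recording <- function(freqs, rate = 250, duration_s = 4, amp = 1,
                           labels = NULL) {
  t <- (seq_len(round(duration_s * rate)) - 1) / rate
  dat <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), t))
  recording(dat, rate, labels)
}

# brute-force narrow-band SNR: direct sum over the K/2 neighbours each side
oracle_snr <- function(F, i, K) {
  ks <- seq_len(K / 2)
  K * F[i] / sum(F[i + ks] + F[i - ks])
}

# brute-force leading canonical correlation on a 2-row x 2-row instance:
# grid search over combination angles
oracle_cca_2x2 <- function(X, Y, n_grid = 2000) {
  ang <- seq(0, pi, length.out = n_grid)
  best <- 0
  for (a in ang) {
    u <- cos(a) * X[1, ] + sin(a) * X[2, ]
    for (b in ang[seq(1, n_grid, by = 25)]) {
      v <- cos(b) * Y[1, ] + sin(b) * Y[2, ]
      r <- abs(cor(u, v))
      if (is.finite(r) && r > best) best <- r
    }
  }
  best
}

# brute-force ridge solution of a lagged regression, built sample by sample
oracle_ridge_trf <- function(s, x, lags, lambda) {
  n <- length(s)
  valid <- (1 + max(lags)):n
  S <- matrix(0, length(valid), length(lags))
  for (j in seq_along(lags)) {
    for (r in seq_along(valid)) S[r, j] <- s[valid[r] - lags[j]]
  }
  solve(t(S) %*% S + diag(lambda, length(lags)), t(S) %*% x[valid])
}

# epoch trial set with a prescribed number of flat (bad) channels per epoch
epochs_with_bad <- function(bad_counts, n_ch = 10, n_samp = 100, rate = 250) {
  n <- length(bad_counts)
  dat <- array(0, dim = c(n, n_ch, n_samp))
  t <- seq_len(n_samp) / rate
  for (i in seq_len(n)) {
    for (c in seq_len(n_ch)) dat[i, c, ] <- 10 * sin(2 * pi * 10 * t + c)
    if (bad_counts[i] > 0) {
      for (c in seq_len(bad_counts[i])) dat[i, c, ] <- 0   # flat channel
    }
  }
  trial_set(dat, rate, rep(1L, n), list(stimulus_spec(10, 0, n_samp / rate)))
}

# small, fast cocktail config for property tests; ... overrides defaults
small_cocktail_cfg <- function(..., seed = 1) {
  args <- utils::modifyList(
    list(trial_s = 10, env_rate = 64, n_trials = 6, n_channels = 4,
         lag_range_ms = c(0, 300), peak_lags_ms = c(80, 160),
         peak_amps = c(1.2, -0.8), seed = seed),
    list(...)
  )
  do.call(cocktail_sim_config, args)
}

# 99% binomial band for an accuracy under chance p0
chance_band <- function(n, p0) {
  stats::qbinom(c(0.005, 0.995), n, p0) / n
}
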
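test_that("sine/cosine references have the stated shape and structure", {
  sp <- stimulus_spec(10, 0, 4)
  Y <- make_reference(sp, n_harmonics = 5, rate = 250, n_samples = 1000)
  expect_equal(dim(Y), c(10L, 1000L))
  # integer cycles in the window: sin/cos rows of one harmonic orthogonal
  for (h in 1:5) {
    expect_lt(abs(sum(Y[2 * h - 1, ] * Y[2 * h, ])), 1e-8)
  }
  # phase pi flips the sign of odd harmonics only
  Ypi <- make_reference(stimulus_spec(10, pi, 4), 4, 250, 1000)
  Y4 <- make_reference(sp, 4, 250, 1000)
  for (h in 1:4) {
    sgn <- if (h %% 2 == 1) -1 else 1
    expect_equal(Ypi[2 * h - 1, ], sgn * Y4[2 * h - 1, ], tolerance = 1e-9)
    expect_equal(Ypi[2 * h, ], sgn * Y4[2 * h, ], tolerance = 1e-9)
  }
  expect_error(make_reference(sp, 13, 250, 1000), "Nyquist")
})

test_that("canonical correlation matches identities and a brute-force oracle", {
  withr::with_seed(4, {
    y <- rnorm(500)
    X1 <- matrix(y, 1)
    expect_equal(cca_corr(X1, matrix(y, 1)), 1, tolerance = 1e-9)
    a <- rnorm(500); b <- 0.4 * a + rnorm(500)
    expect_equal(cca_corr(matrix(a, 1), matrix(b, 1)), abs(cor(a, b)),
                 tolerance = 1e-9)
    # independent white noise: near zero for long signals
    expect_lt(cca_corr(matrix(rnorm(4000), 2), matrix(rnorm(4000), 2)), 0.1)
    # brute-force maximization over combination angles on 2x2 instances
    for (rep in 1:5) {
      X <- matrix(rnorm(400), 2)
      Y <- matrix(rnorm(400), 2)
      Y[1, ] <- Y[1, ] + 0.5 * X[1, ]
      expect_equal(cca_corr(X, Y), oracle_cca_2x2(X, Y), tolerance = 1e-3)
    }
  })
})

test_that("cca_corr is exact against stats::cancor", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      X <- matrix(rnorm(3 * 300), 3)
      Y <- matrix(rnorm(4 * 300), 4)
      Y[1, ] <- Y[1, ] + 0.3 * X[2, ]
      ref <- stats::cancor(t(X), t(Y))$cor[1]
      expect_equal(cca_corr(X, Y), ref, tolerance = 1e-6)
    }
  })
})

test_that("TRCA recovers a known mixing direction", {
  withr::with_seed(6, {
    m <- c(0.8, 0.6)                      # unit mixing vector, 2 channels
    n_samp <- 400
    src <- rnorm(n_samp)                  # one source, copied across trials
    trials <- lapply(1:6, function(j) {
      outer(m, src) + matrix(rnorm(2 * n_samp, sd = 0.05), 2)
    })
    dat <- array(0, c(6, 2, n_samp))
    for (j in 1:6) dat[j, , ] <- trials[[j]]
    ts <- trial_set(dat, 250, rep(1L, 6), list(stimulus_spec(10)))
    model <- fit_trca(ts, ensemble = FALSE)
    w <- model$filters[[1]][[1]]
    expect_gt(abs(sum(w * m) / sqrt(sum(w^2) * sum(m^2))), 0.99)
  })
})

test_that("TRCA templates are trial means and degenerate input still fits", {
  withr::with_seed(7, {
    x <- matrix(rnorm(3 * 200), 3)
    dat <- array(0, c(4, 3, 200))
    for (j in 1:4) dat[j, , ] <- x          # identical trials
    ts <- trial_set(dat, 250, rep(1L, 4), list(stimulus_spec(10)))
    model <- fit_trca(ts, ensemble = FALSE)
    expect_equal(model$templates[[1]][[1]], x - rowMeans(x),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_length(model$filters[[1]][[1]], 3L)
    expect_error(fit_trca(trial_set(dat[1, , , drop = FALSE], 250, 1L,
                                    list(stimulus_spec(10)))),
                 "at least 2")
  })
})

test_that("TRCA classification returns the matching class with rho = 1 on its template", {
  cfg <- ssvep_sim_config(seed = 2, noise_rms_uV = 0.5, trial_s = 2,
                          n_blocks = 3)
  ts <- simulate_ssvep_trials(cfg)
  model <- fit_trca(ts)
  for (cls in c(1L, 5L, 9L)) {
    res <- classify_trca(model, model$templates[[1]][[cls]])
    expect_identical(res$class_index, cls)
    expect_equal(res$coefficients[cls], 1, tolerance = 1e-9)
  }
  # noiseless 10 Hz trial classified as the 10 Hz class (index 5)
  clean <- ssvep_sim_config(seed = 2, noise_rms_uV = 0, trial_s = 2,
                            n_blocks = 1)
  one <- simulate_ssvep_trials(clean)
  i10 <- which(one$labels == 5)
  expect_identical(classify_trca(model, one$data[i10, , ])$class_index, 5L)
})

test_that("classification is invariant to trial and filter scaling", {
  cfg <- ssvep_sim_config(seed = 8, trial_s = 2, n_blocks = 3)
  ts <- simulate_ssvep_trials(cfg)
  model <- fit_trca(ts)
  X <- ts$data[1, , ]
  base <- classify_trca(model, X)
  scaled <- classify_trca(model, 3.7 * X)
  expect_equal(scaled$coefficients, base$coefficients, tolerance = 1e-9)
  model2 <- model
  model2$filters <- lapply(model$filters, function(fl) lapply(fl, `*`, 5))
  expect_equal(classify_trca(model2, X)$coefficients, base$coefficients,
               tolerance = 1e-9)
  fb <- filter_bank_spec(3)
  s1 <- classify_fbcca(X, ts$stimuli, ts$rate, fb)
  s2 <- classify_fbcca(0.25 * X, ts$stimuli, ts$rate, fb)
  expect_equal(s2$scores, s1$scores, tolerance = 1e-7)
  expect_identical(s2$class_index, s1$class_index)
})

test_that("FBCCA identifies a noiseless trial with a strict score margin", {
  cfg <- ssvep_sim_config(seed = 1, noise_rms_uV = 0, trial_s = 2,
                          n_blocks = 1)
  ts <- simulate_ssvep_trials(cfg)
  i12 <- which(vapply(ts$labels, function(l) ts$stimuli[[l]]$frequency_hz,
                      numeric(1)) == 12)
  res <- classify_fbcca(ts$data[i12, , ], ts$stimuli, ts$rate)
  expect_identical(res$class_index, ts$labels[i12])
  expect_true(all(res$scores[-res$class_index] < res$scores[res$class_index]))
})

test_that("FBCCA ties between identical stimulus specs break to the lowest index", {
  cfg <- ssvep_sim_config(seed = 1, noise_rms_uV = 0,
                          class_table = list(stimulus_spec(10, 0, 2),
                                             stimulus_spec(10, 0, 2)),
                          trial_s = 2, n_blocks = 1)
  ts <- simulate_ssvep_trials(cfg)
  res <- classify_fbcca(ts$data[1, , ], ts$stimuli, ts$rate)
  expect_identical(res$class_index, 1L)
  expect_equal(res$scores[1], res$scores[2], tolerance = 1e-12)
})

test_that("leave-one-block-out folds never leak and count correctly", {
  cfg <- ssvep_sim_config(seed = 4, noise_rms_uV = 0.2, trial_s = 1,
                          class_table = class_table_9(1)[c(1, 5, 9)],
                          n_blocks = 6)
  ts <- simulate_ssvep_trials(cfg)
  cv <- cross_validate(ts, "trca", n_train_blocks = 5)
  expect_length(cv$fold_accuracy, 6L)
  expect_equal(nrow(cv$predictions), n_trials(ts))
  expect_equal(cv$accuracy, 1)                 # near-noiseless, separable
  expect_error(cross_validate(ts, "trca", n_train_blocks = 6), "blocks")
  no_blocks <- trial_set(ts$data, ts$rate, ts$labels, ts$stimuli)
  expect_error(cross_validate(no_blocks, "trca"), "block")
})

test_that("label shuffling drives both decoders to chance", {
  cfg <- ssvep_sim_config(seed = 10, trial_s = 1,
                          class_table = class_table_9(1)[c(1, 5, 9)],
                          n_blocks = 6)
  ts <- simulate_ssvep_trials(cfg)
  withr::with_seed(99, {
    ts$labels <- sample(ts$labels)
  })
  band <- chance_band(n_trials(ts), 1 / 3)
  acc_t <- cross_validate(ts, "trca")$accuracy
  acc_f <- cross_validate(ts, "fbcca", filter_bank = filter_bank_spec(2),
                          n_harmonics = 2)$accuracy
  expect_gte(acc_t, band[1]); expect_lte(acc_t, band[2])
  expect_gte(acc_f, band[1]); expect_lte(acc_f, band[2])
})

test_that("decoder accuracy does not increase with noise", {
  levels <- c(0.5, 3, 12)
  seeds <- 1:20
  small_tab <- class_table_9(1)[c(1, 5, 9)]
  mean_acc <- function(noise, method) {
    mean(vapply(seeds, function(s) {
      cfg <- ssvep_sim_config(seed = s, noise_rms_uV = noise, trial_s = 1,
                              class_table = small_tab, n_blocks = 3,
                              channel_labels = c("L1", "L2", "R1", "R2"))
      ts <- simulate_ssvep_trials(cfg)
      if (method == "trca") {
        cross_validate(ts, "trca", n_train_blocks = 2)$accuracy
      } else {
        cross_validate(ts, "fbcca", filter_bank = filter_bank_spec(2),
                       n_harmonics = 2)$accuracy
      }
    }, numeric(1)))
  }
  for (method in c("trca", "fbcca")) {
    accs <- vapply(levels, mean_acc, numeric(1), method = method)
    expect_true(all(diff(accs) <= 0.03),
                info = paste(method, paste(round(accs, 3), collapse = " ")))
  }
})
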
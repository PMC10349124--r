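# SSVEP target identification. Two routes share the same decision rule —
# the class whose template correlates best with the spatially filtered
# trial wins:
#   rho(f) = corr(Wz' Z(f), Wx' X)
# TRCA learns the spatial filters from training data (maximizing inter-trial
# covariance of the task response) and uses trial-averaged templates; FBCCA
# is calibration-free, correlating sub-band-filtered trials against
# sine/cosine references via canonical correlation.

#' Filter-bank specification for sub-band decomposition
#'
#' The standard speller filter bank: sub-band `m` spans `8 m` Hz to a
#' common upper edge (88 Hz), and sub-band scores are combined with weights
#' `a(m) = m^-1.25 + 0.25`, emphasising the low sub-bands where SSVEP
#' energy concentrates.
#'
#' @param n_subbands number of sub-bands (default 5).
#' @param band_edges_hz optional n x 2 matrix of (lo, hi) edges overriding
#'   the default; must lie inside (0, Nyquist) at use time.
#' @param weights optional positive per-sub-band weights.
#' @param upper_hz common upper edge for the default bank (default 88).
#' @return list of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(n_subbands = 5, band_edges_hz = NULL,
                             weights = NULL, upper_hz = 88) {
  stopifnot(n_subbands >= 1)
  if (is.null(band_edges_hz)) {
    band_edges_hz <- cbind(8 * seq_len(n_subbands), upper_hz)
  }
  band_edges_hz <- matrix(band_edges_hz, ncol = 2)
  if (nrow(band_edges_hz) != n_subbands ||
      any(band_edges_hz[, 1] >= band_edges_hz[, 2]) ||
      any(band_edges_hz[, 1] <= 0)) {
    stop("band_edges_hz must be n_subbands rows of 0 < lo < hi")
  }
  if (is.null(weights)) {
    m <- seq_len(n_subbands)
    weights <- m^(-1.25) + 0.25
  }
  if (any(weights <= 0) || length(weights) != n_subbands) {
    stop("weights must be positive, one per sub-band")
  }
  structure(list(n_subbands = n_subbands, band_edges_hz = band_edges_hz,
                 weights = weights), class = "filter_bank_spec")
}

subband_filter <- function(X, rate, edges) {
  hi <- min(edges[2], rate / 2 * 0.95)
  bp_matrix(X, rate, edges[1], hi, order = 4)
}

# centre each row (channel) of a trial
center_rows <- function(X) X - rowMeans(X)

trca_filter_one <- function(trials_cls) {
  # trials_cls: list of channels x samples matrices (>= 2), row-centred
  Q <- 0; Ssum <- 0
  xs <- 0
  for (x in trials_cls) {
    Q <- Q + tcrossprod(x)
    xs <- xs + x
  }
  S <- tcrossprod(xs) - Q                    # sum over j1 != j2 of x_j1 x_j2'
  Qi <- tryCatch(solve(Q), error = function(e) {
    jit <- 1e-8 * sum(diag(Q)) / nrow(Q)
    earbci_log("fit_trca: singular Q, ridge jitter ", signif(jit, 3), " added")
    solve(Q + diag(jit, nrow(Q)))
  })
  e <- eigen(Qi %*% S)
  w <- Re(e$vectors[, which.max(Re(e$values))])
  w / sqrt(sum(w^2))
}

#' Fit a TRCA model
#'
#' For each class, with row-centred training trials `x_j`
#' (channels x samples), task-related component analysis maximizes the
#' inter-trial covariance: `S = sum_{j1 != j2} x_j1 x_j2'`,
#' `Q = sum_j x_j x_j'`, and the spatial filter is the principal
#' generalized eigenvector of `S w = lambda Q w`. The class template is the
#' arithmetic mean of the training trials. With `ensemble = TRUE`
#' (default), all class filters are stacked and shared at test time; with a
#' filter bank, filters and templates are fitted per sub-band and sub-band
#' correlations are combined with the bank weights.
#'
#' @param train a [trial_set()] with at least 2 trials per class.
#' @param filter_bank a [filter_bank_spec()], or `NULL` for broadband.
#' @param ensemble use the ensemble variant (stack all class filters).
#' @return object of class `trca_model`.
#' @export
fit_trca <- function(train, filter_bank = NULL, ensemble = TRUE) {
  stopifnot(inherits(train, "trial_set"))
  n_cls <- length(train$stimuli)
  counts <- tabulate(train$labels, n_cls)
  present <- which(counts > 0)
  if (any(counts[present] < 2)) {
    stop("fit_trca requires at least 2 training trials per class")
  }
  n_sb <- if (is.null(filter_bank)) 1L else filter_bank$n_subbands
  earbci_log("fit_trca: ", length(present), " classes, ", n_sb,
             " sub-band(s), ensemble=", ensemble)
  # per sub-band: list over classes of filters and templates
  filters <- vector("list", n_sb)
  templates <- vector("list", n_sb)
  for (m in seq_len(n_sb)) {
    trial_of <- function(i) {
      x <- train$data[i, , , drop = TRUE]
      if (is.vector(x)) x <- matrix(x, nrow = dim(train$data)[2])
      if (!is.null(filter_bank)) {
        x <- subband_filter(x, train$rate, filter_bank$band_edges_hz[m, ])
      }
      center_rows(x)
    }
    fl <- vector("list", n_cls)
    tp <- vector("list", n_cls)
    for (cls in present) {
      idx <- which(train$labels == cls)
      xs <- lapply(idx, trial_of)
      fl[[cls]] <- trca_filter_one(xs)
      tp[[cls]] <- Reduce(`+`, xs) / length(xs)
    }
    filters[[m]] <- fl
    templates[[m]] <- tp
  }
  structure(list(filters = filters, templates = templates,
                 ensemble = ensemble, filter_bank = filter_bank,
                 class_table = train$stimuli, classes = present,
                 rate = train$rate, n_samples = dim(train$data)[3],
                 channel_labels = train$channel_labels),
            class = "trca_model")
}

# Pearson correlation that tolerates zero variance (returns 0, logged)
safe_cor <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (sd(a) == 0 || sd(b) == 0) {
    earbci_log("correlation of a zero-variance signal defined as 0")
    return(0)
  }
  cor(a, b)
}

#' Classify one trial with a fitted TRCA model
#'
#' Computes, per class `f`, the Pearson correlation between the spatially
#' filtered test trial and the filtered template; under the ensemble
#' variant the filters of all classes are applied jointly and the
#' correlation is taken over the stacked components. With a filter bank,
#' per-sub-band correlations are combined as `sum_m a(m) rho_m`. The
#' predicted class is the argmax; ties break to the lowest class index.
#'
#' @param model a `trca_model` from [fit_trca()].
#' @param X channels x samples test trial matching the training window.
#' @return list with `class_index` and `coefficients` (one rho per class).
#' @export
classify_trca <- function(model, X) {
  stopifnot(is.matrix(X), nrow(X) == length(model$channel_labels))
  if (ncol(X) != model$n_samples) {
    stop("test trial has ", ncol(X), " samples; model expects ",
         model$n_samples)
  }
  n_cls <- length(model$class_table)
  n_sb <- if (is.null(model$filter_bank)) 1L else model$filter_bank$n_subbands
  wts <- if (is.null(model$filter_bank)) 1 else model$filter_bank$weights
  rho <- rep(-Inf, n_cls)
  for (cls in model$classes) rho[cls] <- 0
  for (m in seq_len(n_sb)) {
    Xm <- if (is.null(model$filter_bank)) X else {
      subband_filter(X, model$rate, model$filter_bank$band_edges_hz[m, ])
    }
    Xm <- center_rows(Xm)
    W <- if (model$ensemble) {
      do.call(cbind, model$filters[[m]][model$classes])  # channels x n_cls
    } else NULL
    for (cls in model$classes) {
      Wc <- if (model$ensemble) W else matrix(model$filters[[m]][[cls]])
      fx <- crossprod(Wc, Xm)
      fz <- crossprod(Wc, model$templates[[m]][[cls]])
      rho[cls] <- rho[cls] + wts[m] * safe_cor(fx, fz)
    }
  }
  list(class_index = which.max(rho), coefficients = rho)
}

#' Sine/cosine reference signals for one stimulus
#'
#' Rows `sin(2 pi h f t + h phi)` and `cos(2 pi h f t + h phi)` for
#' harmonics `h = 1..n_harmonics`, the calibration-free template of
#' CCA-based SSVEP decoding. Harmonic phase is locked as `h * phi`.
#'
#' @param spec a [stimulus_spec()].
#' @param n_harmonics number of harmonics (all below Nyquist).
#' @param rate sampling rate in Hz.
#' @param n_samples reference length in samples.
#' @return a `2 * n_harmonics` x `n_samples` matrix.
#' @export
make_reference <- function(spec, n_harmonics, rate, n_samples) {
  if (n_harmonics * spec$frequency_hz >= rate / 2) {
    stop("harmonic ", n_harmonics, " of ", spec$frequency_hz,
         " Hz is at or above Nyquist")
  }
  t <- (seq_len(n_samples) - 1) / rate
  Y <- matrix(0, 2 * n_harmonics, n_samples)
  for (h in seq_len(n_harmonics)) {
    ph <- 2 * pi * h * spec$frequency_hz * t + h * spec$phase_rad
    Y[2 * h - 1, ] <- sin(ph)
    Y[2 * h, ] <- cos(ph)
  }
  Y
}

#' Leading canonical correlation between two multichannel signals
#'
#' The maximal Pearson correlation achievable between linear combinations
#' of the rows of `X` and rows of `Y`. Covariance matrices are
#' symmetrized-whitened via eigendecomposition with a small trace-scaled
#' ridge when rank-deficient (logged).
#'
#' @param X channels x samples matrix.
#' @param Y references x samples matrix, same sample count.
#' @return leading canonical correlation in `[0, 1]`.
#' @export
cca_corr <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  stopifnot(ncol(X) == ncol(Y))
  n <- ncol(X)
  X <- center_rows(X); Y <- center_rows(Y)
  Cxx <- tcrossprod(X) / n
  Cyy <- tcrossprod(Y) / n
  Cxy <- tcrossprod(X, Y) / n
  isqrt <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    tol <- 1e-10 * max(e$values, 0)
    if (any(e$values <= tol)) {
      ridge <- 1e-8 * sum(diag(C)) / nrow(C) + 1e-300
      earbci_log("cca_corr: rank-deficient covariance, ridge ",
                 signif(ridge, 3), " added")
      e <- eigen(C + diag(ridge, nrow(C)), symmetric = TRUE)
    }
    e$vectors %*% diag(1 / sqrt(e$values), nrow(C)) %*% t(e$vectors)
  }
  M <- isqrt(Cxx) %*% Cxy %*% isqrt(Cyy)
  s <- svd(M)$d[1]
  min(max(s, 0), 1)
}

#' Calibration-free FBCCA classification of one trial
#'
#' For each candidate class `f`, the trial is filtered into the bank's
#' sub-bands and the leading canonical correlation `rho_f^(m)` against the
#' sine/cosine reference of `f` is computed per sub-band `m`; the class
#' score is `sum_m a(m) * rho_f^(m)^2` and the argmax wins (ties to the
#' lowest class index, logged). No training data is used.
#'
#' @param X channels x samples trial.
#' @param class_table list of [stimulus_spec()] candidates.
#' @param rate sampling rate in Hz.
#' @param fb a [filter_bank_spec()].
#' @param n_harmonics reference harmonics (default 5).
#' @return list with `class_index` and `scores`.
#' @export
classify_fbcca <- function(X, class_table, rate, fb = filter_bank_spec(),
                           n_harmonics = 5) {
  stopifnot(is.matrix(X), length(class_table) >= 1)
  n_samp <- ncol(X)
  refs <- lapply(class_table, function(sp) {
    nh <- n_harmonics
    while (nh > 1 && nh * sp$frequency_hz >= rate / 2) nh <- nh - 1
    make_reference(sp, nh, rate, n_samp)
  })
  Xm_list <- lapply(seq_len(fb$n_subbands), function(m) {
    subband_filter(X, rate, fb$band_edges_hz[m, ])
  })
  scores <- vapply(seq_along(class_table), function(f) {
    s <- 0
    for (m in seq_len(fb$n_subbands)) {
      r <- cca_corr(Xm_list[[m]], refs[[f]])
      s <- s + fb$weights[m] * r^2
    }
    s
  }, numeric(1))
  best <- which.max(scores)
  dup <- which(abs(scores - scores[best]) < 1e-15)
  if (length(dup) > 1L) {
    earbci_log("classify_fbcca: score tie between classes ",
               paste(dup, collapse = ","), "; lowest index chosen")
    best <- min(dup)
  }
  list(class_index = best, scores = scores)
}

#' Leave-one-block-out cross-validation of an SSVEP decoder
#'
#' Each fold holds out one stimulation block for testing; the model is
#' fitted on `n_train_blocks` of the remaining blocks (the most recent
#' ones, default all remaining, capped at 5 as in a 6-block design with 5
#' training blocks). FBCCA needs no training and is simply evaluated per
#' fold. No test trial ever appears in its fold's training set.
#'
#' @param trials a [trial_set()] with block indices.
#' @param method `"trca"` or `"fbcca"`.
#' @param n_train_blocks training blocks per fold (default
#'   `min(5, n_blocks - 1)`).
#' @param filter_bank [filter_bank_spec()] or `NULL`; default `NULL` for
#'   TRCA (broadband) and the standard bank for FBCCA.
#' @param ensemble ensemble TRCA flag.
#' @param n_harmonics FBCCA reference harmonics.
#' @return list with `fold_accuracy`, `accuracy` (pooled), and
#'   `predictions` (data frame: trial, block, true, predicted).
#' @export
cross_validate <- function(trials, method = c("trca", "fbcca"),
                           n_train_blocks = NULL, filter_bank = NULL,
                           ensemble = TRUE, n_harmonics = 5) {
  method <- match.arg(method)
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(trials$blocks)) stop("cross_validate requires block labels")
  blocks <- sort(unique(trials$blocks))
  if (is.null(n_train_blocks)) n_train_blocks <- min(5L, length(blocks) - 1L)
  if (length(blocks) - 1L < n_train_blocks || n_train_blocks < 1L) {
    stop("need at least n_train_blocks + 1 = ", n_train_blocks + 1,
         " blocks; have ", length(blocks))
  }
  if (method == "fbcca" && is.null(filter_bank)) filter_bank <- filter_bank_spec()
  earbci_log("cross_validate: ", method, ", ", length(blocks), " folds, ",
             n_train_blocks, " training blocks each")
  preds <- data.frame(trial = integer(0), block = integer(0),
                      true = integer(0), predicted = integer(0))
  fold_acc <- numeric(length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    test_idx <- which(trials$blocks == b)
    train_blocks <- utils::tail(setdiff(blocks, b), n_train_blocks)
    if (method == "trca") {
      tr_idx <- which(trials$blocks %in% train_blocks)
      sub <- trial_set(trials$data[tr_idx, , , drop = FALSE], trials$rate,
                       trials$labels[tr_idx], trials$stimuli,
                       trials$channel_labels, trials$blocks[tr_idx])
      model <- fit_trca(sub, filter_bank = filter_bank, ensemble = ensemble)
    }
    p <- integer(length(test_idx))
    for (k in seq_along(test_idx)) {
      X <- trials$data[test_idx[k], , , drop = TRUE]
      if (is.vector(X)) X <- matrix(X, nrow = dim(trials$data)[2])
      p[k] <- if (method == "trca") {
        classify_trca(model, X)$class_index
      } else {
        classify_fbcca(X, trials$stimuli, trials$rate, filter_bank,
                       n_harmonics)$class_index
      }
    }
    fold_acc[bi] <- mean(p == trials$labels[test_idx])
    preds <- rbind(preds, data.frame(trial = test_idx, block = b,
                                     true = trials$labels[test_idx],
                                     predicted = p))
  }
  list(fold_accuracy = fold_acc, accuracy = mean(preds$predicted == preds$true),
       predictions = preds)
}
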
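#' One-sided power spectral density
#'
#' Periodogram or Welch estimate with Parseval-consistent scaling: for the
#' windowless periodogram, `sum(F) * delta_f` equals the mean square of the
#' signal. The periodogram bin spacing is `rate / n`; Welch splits the signal
#' into Hann-windowed segments with 50\% overlap and averages, trading
#' frequency resolution for variance.
#'
#' @param x numeric vector, or channels x samples matrix (a PSD is computed
#'   per channel).
#' @param rate sampling rate in Hz.
#' @param method `"periodogram"` or `"welch"`.
#' @param n_segments number of Welch segments (default 8).
#' @return a list of class `psd_spectrum` with `freq` (Hz), `F` (density,
#'   uV^2/Hz; a vector, or frequency x channel matrix for matrix input),
#'   `rate` and `df` (bin spacing).
#' @export
psd <- function(x, rate, method = c("periodogram", "welch"), n_segments = 8) {
  method <- match.arg(method)
  if (inherits(x, "eeg_recording")) { rate <- x$rate; x <- x$data }
  if (is.matrix(x)) {
    per_ch <- apply(x, 1, function(ch) psd(ch, rate, method, n_segments),
                    simplify = FALSE)
    out <- per_ch[[1]]
    out$F <- vapply(per_ch, `[[`, numeric(length(out$F)), "F")
    return(out)
  }
  if (length(x) == 0L) stop("psd: empty signal")
  if (method == "periodogram") {
    sp <- periodogram_onesided(x, rate)
  } else {
    seg_len <- max(8L, floor(length(x) / ((n_segments + 1) / 2)))
    hop <- floor(seg_len / 2)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
    starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
    acc <- NULL
    for (s in starts) {
      seg <- x[s + seq_len(seg_len) - 1L] * w
      p <- periodogram_onesided(seg, rate)
      # undo the window's power loss so a white signal keeps its level
      p$F <- p$F / mean(w^2)
      acc <- if (is.null(acc)) p$F else acc + p$F
    }
    sp <- periodogram_onesided(x[seq_len(seg_len)], rate)
    sp$F <- acc / length(starts)
  }
  structure(c(sp, list(method = method)), class = "psd_spectrum")
}

periodogram_onesided <- function(x, rate) {
  n <- length(x)
  X <- fft(x)
  n_keep <- floor(n / 2) + 1L
  F <- (Mod(X[seq_len(n_keep)])^2) / (n * rate)
  # double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, n_keep); dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_keep] <- 1
  F <- F * dbl
  list(freq = (seq_len(n_keep) - 1L) * rate / n, F = F,
       rate = rate, df = rate / n)
}

#' Narrow-band signal-to-noise ratio at one frequency
#'
#' The SSVEP SNR at a stimulation frequency `f` treats the spectral density
#' at the `K` neighbouring bins (`K/2` on each side) as the noise floor:
#'
#' \deqn{SNR = \frac{K \cdot F(f)}{\sum_{k=1}^{K/2} [F(f + k\Delta f) + F(f - k\Delta f)]}}
#'
#' so a flat spectrum has SNR exactly 1. `f_hz` is snapped to the nearest
#' grid bin; the offset is logged. `K` must be even and the bin needs `K/2`
#' neighbours on each side.
#'
#' @param spec a `psd_spectrum` from [psd()] (vector-valued `F`, i.e. one
#'   channel, or a matrix in which case the SNR is returned per channel).
#' @param f_hz target frequency in Hz.
#' @param K even number of neighbouring bins (default 4).
#' @return SNR value (or vector, one per channel).
#' @export
narrowband_snr <- function(spec, f_hz, K = 4) {
  if (K %% 2 != 0 || K < 2) stop("K must be an even integer >= 2")
  i <- which.min(abs(spec$freq - f_hz))
  off <- spec$freq[i] - f_hz
  if (abs(off) > 1e-12) {
    earbci_log("narrowband_snr: f = ", f_hz, " Hz snapped to grid bin ",
               spec$freq[i], " Hz (offset ", signif(off, 3), " Hz)")
  }
  half <- K / 2
  if (i - half < 1L || i + half > length(spec$freq)) {
    stop("narrowband_snr: f = ", f_hz,
         " Hz lacks K/2 spectral neighbours on both sides")
  }
  Fm <- if (is.matrix(spec$F)) spec$F else matrix(spec$F, ncol = 1)
  ks <- seq_len(half)
  num <- K * Fm[i, ]
  den <- colSums(Fm[i + ks, , drop = FALSE]) + colSums(Fm[i - ks, , drop = FALSE])
  out <- num / den
  if (!is.matrix(spec$F)) out <- out[[1]]
  out
}

#' SNR spectrum over the whole frequency grid
#'
#' Applies [narrowband_snr()] at every interior bin (those with `K/2`
#' neighbours on both sides), yielding the SNR-vs-frequency curve used to
#' compare montages across the 9-target frequency set.
#'
#' @inheritParams narrowband_snr
#' @return list with `freq` and `snr` (vector, or frequency x channel
#'   matrix), plus `K`.
#' @export
snr_spectrum <- function(spec, K = 4) {
  if (K %% 2 != 0 || K < 2) stop("K must be an even integer >= 2")
  half <- K / 2
  idx <- (half + 1L):(length(spec$freq) - half)
  Fm <- if (is.matrix(spec$F)) spec$F else matrix(spec$F, ncol = 1)
  ks <- seq_len(half)
  snr <- vapply(idx, function(i) {
    K * Fm[i, ] / (colSums(Fm[i + ks, , drop = FALSE]) +
                   colSums(Fm[i - ks, , drop = FALSE]))
  }, numeric(ncol(Fm)))
  snr <- if (ncol(Fm) == 1L) as.numeric(snr) else t(snr)
  list(freq = spec$freq[idx], snr = snr, K = K)
}

#' Information transfer rate of an M-class selection
#'
#' Bits per selection follow the standard BCI formula
#' \deqn{B = \log_2 M + P \log_2 P + (1 - P)\log_2\frac{1-P}{M-1}}
#' with the conventions \eqn{x \log_2 x \to 0} at \eqn{P = 0} and
#' \eqn{P = 1}. The rate divides by the total selection time — the decision
#' window plus a gaze-shift interval (default 0.5 s, the speller
#' convention) — and is reported in bits per minute. Below-chance
#' accuracies give a negative rate, returned as-is with `below_chance`
#' flagged.
#'
#' @param M number of classes (>= 2).
#' @param P accuracy in `[0, 1]`.
#' @param T_s decision-window length in seconds.
#' @param gaze_shift_s extra per-selection time in seconds (default 0.5).
#' @return a list of class `itr_result` with `M`, `P`, `T_total_s`,
#'   `bits_per_selection`, `bits_per_min`, `below_chance`.
#' @export
itr <- function(M, P, T_s, gaze_shift_s = 0.5) {
  if (M < 2) stop("itr: M must be >= 2")
  if (P < 0 || P > 1) stop("itr: P must lie in [0, 1]")
  T_total <- T_s + gaze_shift_s
  if (T_total <= 0) stop("itr: total selection time must be positive")
  xlog2 <- function(x) if (x <= 0) 0 else x * log2(x)
  bits <- log2(M) + xlog2(P) +
    (if (P >= 1) 0 else (1 - P) * log2((1 - P) / (M - 1)))
  below <- P < 1 / M
  if (below) earbci_log("itr: accuracy ", P, " below chance 1/", M,
                        "; negative rate returned unclamped")
  structure(list(M = M, P = P, T_total_s = T_total,
                 bits_per_selection = bits,
                 bits_per_min = 60 * bits / T_total,
                 below_chance = below),
            class = "itr_result")
}

#' @export
print.itr_result <- function(x, ...) {
  cat(sprintf("ITR: M=%d, P=%.4f, T=%.2f s -> %.2f bits/min%s\n",
              x$M, x$P, x$T_total_s, x$bits_per_min,
              if (x$below_chance) " (below chance)" else ""))
  invisible(x)
}
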
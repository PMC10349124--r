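---
title: "Methods: simulation and decoding of in-ear EEG BCI paradigms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and decoding of in-ear EEG BCI paradigms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earbci)
```

## Scope

`earbci` implements the signal-processing and decoding chain of an in-ear
EEG brain-computer interface study: steady-state visual evoked potential
(SSVEP) target identification, narrow-band SNR and information-transfer-rate
metrics, and cocktail-party auditory attention decoding (AAD) by
temporal-response-function (TRF) modeling. Because recorded sessions are
large and external, the package ships a synthetic-EEG generator that
reproduces the statistical structure the analyses rely on; every pipeline
stage is exercised end to end on generated data by the test suite and the
`analysis/` scripts.

## SSVEP decoding

A flickering target at frequency $f$ evokes a periodic EEG response at $f$
and its harmonics. Both decoders score a test trial $X$ (channels
$\times$ samples) against per-class templates through spatial filters and
pick the class with the largest coefficient:

$$\rho^{(f)} = \mathrm{corr}\!\left(W_Z^\top Z^{(f)},\; W_X^\top X\right).$$

**TRCA** (task-related component analysis) is the calibrated route. For
each class, with mean-removed training trials $x_j$, it maximizes the
inter-trial covariance of the filtered response: with
$S = \sum_{j_1 \ne j_2} x_{j_1} x_{j_2}^\top$ and
$Q = \sum_j x_j x_j^\top$, the filter is the principal generalized
eigenvector of $S w = \lambda Q w$, and the template $Z^{(f)}$ is the
trial average. The default is the ensemble variant: the filters of all
classes are stacked and shared at test time, which is what the modern
speller literature uses. A filter bank is optional for TRCA (broadband by
default here; the 4 s, 9-class desk-scale problem does not need it) and
always on for FBCCA.

**FBCCA** is calibration-free. The trial is decomposed into $M$ sub-bands
(sub-band $m$ spans $8m$ Hz to a common 88 Hz upper edge; 5 sub-bands by
default), the leading canonical correlation $\rho^{(m)}_f$ between the
sub-band trial and the class's sine/cosine reference set
$\{\sin, \cos\}(2\pi h f t + h\phi)$, $h = 1..5$, is computed per
sub-band, and the class score is $\sum_m a(m)\, (\rho^{(m)}_f)^2$ with
$a(m) = m^{-1.25} + 0.25$. These constants are the standard filter-bank
design; all are configurable. Harmonic phase is locked as $h\phi$,
consistent with a periodic nonlinear response.

Ties break to the lowest class index everywhere, and are logged.
Correlations of zero-variance signals are defined as 0 rather than NA so
degenerate fixtures behave deterministically; matrix inversions fall back
to a trace-scaled ridge ($10^{-8}\,\mathrm{tr}(Q)/p$) when singular.

Cross-validation is leave-one-block-out: each stimulation block is tested
once against a model fitted on (by default) 5 other blocks, so a 6-block
session yields 6 folds and no test trial ever appears in its training
set. A 12-block recorded session would use the same scheme; the 6-block
default is the desk-scale choice, and the fold structure is configurable
because a blocked design admits several equally defensible layouts.

## Metrics

The **narrow-band SNR** at a stimulation frequency $f$ treats the $K$
neighbouring spectral bins ($K/2$ on each side, $K = 4$ by default, $K$
even by construction) as the noise estimate:

$$\mathrm{SNR}(f) = \frac{K \cdot F(f)}
 {\sum_{k=1}^{K/2}\left[F(f + k\Delta f) + F(f - k\Delta f)\right]},$$

computed on a full-trial periodogram ($\Delta f = 1/\text{duration}$),
which is what makes the band "narrow"; Welch averaging is available for
display PSDs only. The periodogram is one-sided and Parseval-consistent
(`sum(F) * df` equals the mean square). Off-grid frequencies snap to the
nearest bin with a logged offset. Multi-channel SNR is computed per
channel and averaged after the ratio; averaging the spectra first is the
other defensible order, and the choice is logged by being explicit in the
code path.

The **information transfer rate** of an $M$-class selection with accuracy
$P$ and selection time $T$ seconds is

$$\mathrm{ITR} = \frac{60}{T}\left(\log_2 M + P\log_2 P +
 (1-P)\log_2\frac{1-P}{M-1}\right) \;\text{bits/min},$$

with $x\log_2 x \to 0$ at $P \in \{0, 1\}$. $T$ is the decision window
plus a gaze-shift interval, default 0.5 s: a published 40-target online
operating point (accuracy 75.57 % at a 6 s window) yields 29.8 bits/min
with $T = 6.5$ s and a noticeably different value with $T = 6$ s, so the
0.5 s convention — standard in the speller literature — is the one
consistent with the reported numbers. It is an explicit parameter.
Below-chance accuracies return the formula value unclamped, flagged, for
transparency; note the two-class formula is positive on both sides of
chance.

## Preprocessing

Continuous data are band-passed before epoching (filtering epochs would
spread edge artifacts into short windows): 0.5–90 Hz for SSVEP analyses,
2–8 Hz as the anti-aliasing/feature band for AAD, then decimated to
250 Hz and 128 Hz respectively. The filter is a 4th-order Butterworth
high-pass/low-pass cascade applied forward-backward, hence zero-phase with
a doubled effective order; the cascade avoids the numerical fragility of a
direct transfer-function band-pass whose lower edge is a tiny fraction of
Nyquist. The channel mean is removed before the high-pass (the filter
removes DC anyway, and centred input keeps `filtfilt` edge transients
small). Resampling is polyphase at a small rational ratio after a
zero-phase anti-aliasing low-pass at 90 % of the target Nyquist.

Epoch cleaning is a documented threshold rule standing in for data-driven
artifact search, which needs sensor geometry and search heuristics an
in-ear montage does not supply: a channel is bad when its peak-to-peak
amplitude exceeds 200 µV (artifact) or falls below 0.5 µV
(flat/disconnected); an epoch with more than 4 of 10 bad channels is
rejected, otherwise bad channels are replaced by the mean of the epoch's
good channels. Mean interpolation is used because spherical-spline
interpolation is undefined without electrode coordinates; interpolated
samples therefore lie inside the good-channel range at every time point.
For other channel counts the threshold scales as
$\lceil 0.4\, n_\text{ch} \rceil$, logged.

## Auditory attention decoding

The linear model ties the EEG to a stimulus feature $s(t)$ through a
kernel over lags:

$$x(t, n) = \sum_\tau w(\tau, n)\, s(t - \tau) + \varepsilon(t, n).$$

The feature is the **onset envelope**: the audio is decomposed by a bank
of 128 band-pass filters with ERB-spaced centres from 180 to 7246 Hz
(2nd-order Butterworth, one ERB wide — a gammatone-magnitude stand-in),
band powers are smoothed and decimated to 128 Hz, summed to the broadband
envelope, and differentiated with half-wave rectification. Rectification
keeps the onset envelope nonnegative, which is the conventional reading
of "first derivative" for an onset feature. The synthetic generator
produces such envelopes directly as Poisson pulse trains (4 Hz syllabic
rate, 100 ms refractory period, exponential spacing rescaled so the mean
pulse rate is the nominal one) smoothed by a 50 ms Hann kernel.

**Forward TRF estimation** is per-channel ridge regression on the lagged
stimulus design (lags 0–500 ms by default; $\lambda = 0$ is OLS).
**Backward decoding** reverses the roles: the envelope is regressed on
lagged multichannel EEG (EEG 0–250 ms after the stimulus), pooled over
training trials via Gram-matrix accumulation; the ridge penalty is scaled
by the mean diagonal of the pooled Gram matrix (dimensionless grid) and
selected from `c(1e-4, 1e-2, 1)` by inner leave-one-trial-out
cross-validation when not fixed. Ridge replaces the boosting estimator
some AAD toolchains use: it is closed-form, testable against a
normal-equations oracle, and standard in this literature. Rows whose lag
window would leave the data are trimmed from every design, never
zero-padded, and the reconstruction is correspondingly shorter than the
trial (logged).

Classification compares Pearson correlations (on z-scored series) between
the attended decoder's reconstruction and the two candidate envelopes;
the larger wins, ties go to stream A with a flag. The ignored decoder's
correlations are always computed and exported because group-level
diagnostics use all four, but it does not vote — the primary rule is the
attended-decoder argmax, the reading most consistent with a
correlation-comparison decision diagram. Evaluation is leave-one-out over
trials with both decoders refitted per fold, reporting accuracy, the
per-trial attended-minus-ignored correlation difference, and a two-sided
one-sample t-test on those differences.

## The synthetic generator: what it emulates, and what not

SSVEP trials are deterministic harmonic stacks
$\sum_h A_{c,h}\sin(2\pi h f t + h\phi)$ mixed to channels, plus $1/f$
noise (spectral shaping of white noise, exponent 1) and optionally a
band-limited alpha component (9–11 Hz filtered noise, whose narrow-band
nature yields the waxing-waning envelope of eyes-closed alpha). Defaults:
the 9-class 8–12 Hz table in 0.5 Hz steps, 250 Hz, 4 s trials, 6 blocks,
10 in-ear channels, 1 µV fundamental, noise 2 µV RMS ("moderate"); a
40-class grid (8–15.8 Hz in 0.2 Hz steps, phase increment $0.35\pi$) is
available. In-ear channels get a 2nd-harmonic emphasis
($A_2/A_1 = 1.2$ vs 0.6 occipitally) qualitatively emulating the
published in-ear harmonic profile — illustrative, not a claim of exact
amplitudes, since the source figures are graphical.

Cocktail trials are built exactly from the forward model: ground-truth
TRFs (Gaussian bumps, 15 ms SD, attended peaks $+1.2/-0.8$ µV at
80/160 ms, ignored scaled by $1/3$ for top-down attenuation) convolved
with two independent onset envelopes plus pink noise (0.3 µV RMS, "high
SNR"), 60 s at 128 Hz, 24 trials — matching the deposited sessions'
trial counts (23–25 per subject).

The generator does **not** model volume conduction, inter-subject
variability, non-stationary artifacts, eye blinks, or real speech
acoustics. Passing tests therefore demonstrate correctness of the
algorithms and their implementation under the assumed signal model, not
expected performance on recorded data; the published human-data accuracy
figures (95 % offline 9-target, 75.57 % online 40-target, 84 % AAD for
the best subject) require the deposited recordings.

## Numerical notes and limitations

- All generators are bit-deterministic given config and seed; trial
  seeds derive from the session seed so trials are individually
  reproducible.
- Sample indexing is 0-based with half-open epoch windows and time 0 at
  the first sample; event onsets round to the nearest sample to avoid a
  systematic truncation bias.
- EDF output is 16-bit; the round-trip error is bounded by one
  quantization step of the chosen physical range. The EDF subset
  implemented covers continuous equal-rate recordings (one data record);
  labels truncate to 16 characters with a warning.
- Deconvolution conditioning: a backward decoder inverting a smooth
  (Gaussian-bump) kernel can only partially recover the sharp transients
  of an onset envelope — with the default two-bump kernel the noiseless
  self-reconstruction correlation plateaus near 0.94 irrespective of lag
  span or penalty, because the envelope's high-frequency content is
  attenuated below what a finite FIR decoder can re-amplify. This caps
  reconstruction fidelity, not classification: attended/ignored contrasts
  remain large. Single-bump kernels invert essentially exactly.
- The forward-TRF design built from onset envelopes is strongly
  autocorrelated; near-OLS fits are noisy at realistic SNR and a modest
  ridge (relative $\lambda \approx 1$) stabilizes kernels without moving
  bump locations.
- Problem sizes in the tests and scripts (6 blocks, 4 s SSVEP windows;
  24 cocktail trials of 60 s; scaled-down property sweeps at 64–100 Hz)
  are the package's desk-scale study conditions, chosen to make the full
  pipeline runnable in minutes on one CPU.
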
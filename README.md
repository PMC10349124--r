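# earbci

Simulation and decoding pipelines for in-ear EEG brain-computer
interfaces (BCIs), for researchers evaluating ear-EEG decoding algorithms
without access to recorded sessions. The package covers the two paradigms
an in-ear montage (channels L1–L5, R1–R5, mastoids M1/M2, occipital OZ)
is typically benchmarked on:

- **SSVEP target identification.** A flickering target at frequency *f*
  evokes EEG at *f* and its harmonics. Trials are scored by the
  spatial-filter correlation rule
  ρ⁽ᶠ⁾ = corr(W_Zᵀ Z⁽ᶠ⁾, W_Xᵀ X), with the filters and templates from
  **TRCA** (task-related component analysis; calibrated, trial-averaged
  templates, ensemble filters) or from **FBCCA** (filter-bank canonical
  correlation against sine/cosine references; calibration-free). Narrow-band
  SNR, SNR = K·F(f) / Σₖ[F(f+kΔf) + F(f−kΔf)] (K = 4), and the
  information transfer rate
  ITR = (log₂M + P log₂P + (1−P) log₂((1−P)/(M−1)))/T quantify signal
  quality and throughput.
- **Auditory attention decoding (AAD).** In a two-speaker cocktail-party
  setting, the EEG follows the linear TRF model
  x(t,n) = Σ_τ w(τ,n) s(t−τ) + ε(t,n) with s(t) the speech onset
  envelope (ERB-spaced 128-band filterbank, 180–7246 Hz, band-power sum,
  rectified derivative). Forward ridge regression estimates w; backward
  decoders reconstruct s from lagged EEG, and the attended stream is the
  one whose envelope correlates best with the reconstruction
  (leave-one-out over trials).

A synthetic-EEG generator (harmonic SSVEP stacks over 1/f noise,
eyes-closed alpha, and cocktail trials built from ground-truth TRFs)
defines reproducible study conditions so the whole chain — EDF/CSV I/O,
zero-phase filtering, resampling, epoch cleaning by the over-4-of-10
bad-channel rule, decoding, metrics — is testable end to end. See
`vignettes/earbci-methods.Rmd` for the models, defaults and their
rationale.

## Worked example

```r
library(earbci)

# a 6-block, 9-target SSVEP session at 250 Hz (4 s trials, moderate noise)
cfg <- ssvep_sim_config(seed = 1)
trials <- simulate_ssvep_trials(cfg)

cv <- cross_validate(trials, "trca", n_train_blocks = 5)
cv$accuracy
#> [1] 1

itr(M = 9, P = cv$accuracy, T_s = 4)   # 0.5 s gaze shift added
#> ITR: M=9, P=1.0000, T=4.50 s -> 42.27 bits/min

# the published 40-target online operating point
itr(M = 40, P = 0.7557, T_s = 6)
#> ITR: M=40, P=0.7557, T=6.50 s -> 29.80 bits/min

# cocktail-party attention decoding, 24 trials of 60 s at 128 Hz
aad <- loo_evaluate(simulate_cocktail_trials(cocktail_sim_config(seed = 1)))
aad
#> AAD leave-one-out: accuracy 1.000 over 24 trials
#>   corr diff (att - ign): mean 0.5915, t-test p = 5.26e-35
```

On the synthetic defaults both SSVEP decoders and the AAD pipeline are
near ceiling; accuracies degrade monotonically as the generator's noise
RMS is raised (see the property tests).

## Analysis workflow

The `analysis/` scripts run the full study pipeline on generated data and
write tables under `results/` (step 1 first; optional first argument is
the seed):

```sh
Rscript analysis/01_simulate.R 1      # EDF/CSV session files
Rscript analysis/02_spectra_snr.R     # alpha PSD; per-class SNR by montage
Rscript analysis/03_ssvep_decoding.R  # accuracy & ITR vs window length
Rscript analysis/04_aad.R             # forward TRFs; LOO attention decoding
```

Step 2 reproduces the in-ear 2nd-harmonic emphasis the montage is
simulated with (2nd/1st harmonic SNR ratio ≈ 3.0 in-ear vs ≈ 1.0
occipital on seed 1), and step 4 recovers the attended TRF peak at
~80 ms with the 3:1 attended:ignored amplitude contrast.

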
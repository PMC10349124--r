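#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study data.
#
# Produces (a) a 60 s eyes-closed resting recording with a ~10 Hz alpha
# rhythm, (b) a 6-block 9-target SSVEP session (8-12 Hz in 0.5 Hz steps,
# 250 Hz, 4 s trials) over an in-ear + occipital montage, and (c) a
# 24-trial two-speaker cocktail-party session (60 s, 128 Hz). Continuous
# data are written as EDF with CSV event tables, so steps 2-4 exercise the
# same file formats a recorded session would use.

suppressPackageStartupMessages(library(earbci))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

labels <- c(paste0("L", 1:5), paste0("R", 1:5), "OZ")

## resting alpha ------------------------------------------------------------
rest_cfg <- ssvep_sim_config(channel_labels = labels,
                             alpha = list(center_hz = 10, rms_uV = 2,
                                          on = TRUE),
                             seed = seed)
rest <- simulate_alpha_rest(rest_cfg, duration_s = 60)
write_recording(rest, "results/data/rest_alpha.edf", "edf")
sp <- psd(rest$data[1, ], rest$rate)
band <- sp$freq >= 2 & sp$freq <= 40
cat(sprintf("rest: %d ch x %d samples; spectral peak (2-40 Hz) at %.2f Hz\n",
            nrow(rest$data), ncol(rest$data),
            sp$freq[band][which.max(sp$F[band])]))

## 9-target SSVEP session ---------------------------------------------------
ssvep_cfg <- ssvep_sim_config(channel_labels = labels, seed = seed)
trials <- simulate_ssvep_trials(ssvep_cfg)
# lay the trials back out as one continuous recording + event table, the
# shape in which a recorded session arrives
gap_s <- 0.5
step <- ssvep_cfg$trial_s + gap_s
n_samp_total <- ceiling(n_trials(trials) * step * trials$rate)
cont <- matrix(0, length(labels), n_samp_total)
onsets <- (seq_len(n_trials(trials)) - 1) * step
for (i in seq_len(n_trials(trials))) {
  s0 <- round(onsets[i] * trials$rate)
  cont[, s0 + seq_len(dim(trials$data)[3])] <- trials$data[i, , ]
}
rec <- recording(cont, trials$rate, labels)
write_recording(rec, "results/data/ssvep_session.edf", "edf")
ev <- event_table(onset_s = onsets, class_index = trials$labels,
                  frequency_hz = vapply(trials$labels, function(l)
                    trials$stimuli[[l]]$frequency_hz, numeric(1)),
                  phase_rad = 0, duration_s = ssvep_cfg$trial_s)
ev$block <- trials$blocks
write.csv(ev, "results/data/ssvep_events.csv", row.names = FALSE)
cat(sprintf("ssvep: %d trials (%d blocks x %d targets) written\n",
            n_trials(trials), ssvep_cfg$n_blocks,
            length(ssvep_cfg$class_table)))

## cocktail-party session ---------------------------------------------------
aad_cfg <- cocktail_sim_config(seed = seed)
cocktail <- simulate_cocktail_trials(aad_cfg)
for (i in seq_along(cocktail)) {
  tr <- cocktail[[i]]
  stem <- sprintf("results/data/cocktail_trial%02d", i)
  write_recording(tr$eeg, paste0(stem, ".csv"), "csv")
  write.csv(data.frame(stream1 = tr$env_streams[[1]]$values,
                       stream2 = tr$env_streams[[2]]$values),
            paste0(stem, "_envelopes.csv"), row.names = FALSE)
}
truth <- data.frame(trial = seq_along(cocktail),
                    attended = vapply(cocktail, `[[`, integer(1), "attended"))
write.csv(truth, "results/data/cocktail_attended.csv", row.names = FALSE)
cat(sprintf("cocktail: %d trials of %g s at %g Hz written\n",
            aad_cfg$n_trials, aad_cfg$trial_s, aad_cfg$env_rate))
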
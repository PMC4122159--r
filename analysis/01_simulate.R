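#!/usr/bin/env Rscript
# Generate the synthetic four-group dataset used by the downstream analysis
# scripts: speech sweeps (11 CVC words), 10 Hz noise-burst trains, and
# staged go/no-go behavioral sessions, written in the package's tabular
# dialects under results/data/. Tone tuning is regenerated in memory by
# 04_tuning.R (the full lattice is large on disk).

library(aafdiscrim)

n_sites <- 25    # per group; file-based demo scale
seed <- 2026
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

presets <- vpa_presets()
for (g in names(presets)) {
  ds <- generate_group_dataset(presets[[g]], n_sites, seed = derive_seed(seed, label_index(g)),
                               components = c("speech", "train"))
  all_ss <- c(unlist(ds$speech, recursive = FALSE), ds$train)
  write_spike_table(all_ss, file.path(out, paste0(g, "_spikes.csv")))
  for (task in c("consonant", "vowel")) {
    tr <- generate_behavior_sessions(presets[[g]], task, n_subjects = 10,
                                     seed = derive_seed(seed, label_index(g),
                                                        label_index(task)))
    write_behavior_log(tr, file.path(out, paste0(g, "_", task, "_trials.csv")))
  }
  cat(sprintf("%s: %d sites x (11 words + train), behavior logs written\n",
              g, n_sites))
}
write_stimulus_catalog(
  c(speech_catalog(),
    list(train10hz = stimulus_spec("train10hz", "noise_train",
                                   n_bursts = 6, period_ms = 100))),
  file.path(out, "stimulus_catalog.yaml"))
cat("done; tables under", out, "\n")
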
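#!/usr/bin/env Rscript
# Noise-train synchronization (vector strength, per-burst peak rate) from
# the simulated spike tables, plus tone tuning-curve characterization
# (CF, threshold, BW40) from lattice counts regenerated in memory.
# Writes results/train_sync.csv and results/tuning_summary.csv.

library(aafdiscrim)

out <- "results"
train_stim <- stimulus_spec("train10hz", "noise_train", n_bursts = 6,
                            period_ms = 100)
sync_rows <- list()
for (g in group_labels()) {
  tab <- read_spike_table(file.path(out, "data", paste0(g, "_spikes.csv")))
  trains <- tab[vapply(tab, function(s) s$stim_id == "train10hz",
                       logical(1))]
  for (ss in trains) {
    s <- site_train_summary(ss, train_stim)
    sync_rows[[length(sync_rows) + 1L]] <- data.frame(
      group = g, site_id = ss$site_id,
      vs = if (s$vs$defined) s$vs$vs else NA_real_,
      peak_rate_hz = s$peak_rate_hz_mean)
  }
}
sync <- do.call(rbind, sync_rows)
utils::write.csv(sync, file.path(out, "train_sync.csv"), row.names = FALSE)
cat("vector strength by group:\n")
print(aggregate(cbind(vs, peak_rate_hz) ~ group, sync, mean),
      row.names = FALSE, digits = 3)

# tone lattices: regenerate per site (same seeds as the pipeline would use)
tune_rows <- list()
presets <- vpa_presets()
for (g in names(presets)) {
  ds <- generate_group_dataset(presets[[g]], 25,
                               seed = derive_seed(2026, label_index(g)),
                               components = "tuning")
  for (i in seq_along(ds$tuning)) {
    ts <- tuning_summary(ds$tuning[[i]])
    tune_rows[[length(tune_rows) + 1L]] <- data.frame(
      group = g, site_id = ds$site_ids[i], cf_hz = ts$cf_hz,
      threshold_db = ts$threshold_db, bw40_octaves = ts$bw40_octaves)
  }
}
tuning <- do.call(rbind, tune_rows)
utils::write.csv(tuning, file.path(out, "tuning_summary.csv"),
                 row.names = FALSE)
cat("tone threshold / BW40 by group:\n")
print(aggregate(cbind(threshold_db, bw40_octaves) ~ group, tuning, mean),
      row.names = FALSE, digits = 3)
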
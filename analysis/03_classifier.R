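#!/usr/bin/env Rscript
# Single-sweep PSTH nearest-neighbor discrimination of consonant pairs
# (40 x 1-ms onset bins, leave-one-out templates), per site and pair.
# Writes results/classifier_pairs.csv and results/classifier_sites.csv.

library(aafdiscrim)

out <- "results"
site_rows <- list(); pair_rows <- list()
for (g in group_labels()) {
  tab <- read_spike_table(file.path(out, "data", paste0(g, "_spikes.csv")))
  speech <- tab[vapply(tab, function(s) s$stim_id %in% consonant_labels(),
                       logical(1))]
  by_site <- split(speech, vapply(speech, `[[`, "", "site_id"))
  for (site in names(by_site)) {
    sd_ <- by_site[[site]]
    names(sd_) <- vapply(sd_, `[[`, "", "stim_id")
    s <- all_pairs_summary(sd_, consonant_labels())
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      group = g, site_id = site,
      classifier_pc = s$mean_percent_correct)
    p <- s$pairs; p$group <- g; p$site_id <- site
    pair_rows[[length(pair_rows) + 1L]] <- p
  }
}
sites <- do.call(rbind, site_rows)
utils::write.csv(sites, file.path(out, "classifier_sites.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, pair_rows),
                 file.path(out, "classifier_pairs.csv"), row.names = FALSE)
agg <- aggregate(classifier_pc ~ group, sites, mean)
cat("mean consonant-pair percent correct by group:\n")
print(agg, row.names = FALSE, digits = 3)
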
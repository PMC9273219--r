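#!/usr/bin/env Rscript
# Spectral structure of the cohorts: per-worm mean PSDs, condition-mean
# normalized PSDs with cumulative curves, and per-worm 40% spectral edges.

library(wormdyn)

manifest <- read.csv("results/cohort_manifest.csv")
psd_by_cond <- list()
edges <- NULL
for (k in seq_len(nrow(manifest))) {
  tr <- load_traces(manifest$path[k])
  d <- normalize_dff(tr)
  p <- compute_psd(d)
  cond <- manifest$condition[k]
  psd_by_cond[[cond]] <- c(psd_by_cond[[cond]], list(p))
  edges <- rbind(edges, data.frame(
    trial_id = manifest$trial_id[k], condition = cond,
    spectral_edge_40 = spectral_edge(mean_normalized_psd(list(p)), 0.4)))
}
write.csv(edges, "results/spectral_edges.csv", row.names = FALSE)

curves <- NULL
for (cond in names(psd_by_cond)) {
  m <- mean_normalized_psd(psd_by_cond[[cond]])
  curves <- rbind(curves, data.frame(condition = cond, freq_hz = m$freqs,
                                     power = m$power,
                                     cumulative = m$cumulative))
}
write.csv(curves, "results/mean_psd_curves.csv", row.names = FALSE)
cat("mean 40% spectral edge by condition (Hz):\n")
print(tapply(edges$spectral_edge_40, edges$condition, mean))
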
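#!/usr/bin/env Rscript
# Pairwise correlation structure of the 40 most dynamically active neurons:
# TV differentials, condensed Pearson vectors, +/-0.2 tail proportions and
# pooled per-condition histograms.

library(wormdyn)

manifest <- read.csv("results/cohort_manifest.csv")
props <- NULL
sets_by_cond <- list()
for (k in seq_len(nrow(manifest))) {
  tr <- load_traces(manifest$path[k])
  d <- normalize_dff(tr)
  sel <- select_active_neurons(d, 40)
  ddt <- tv_differentiate(d$dff[sel, ], sampling_rate = d$sampling_rate)
  pc <- pairwise_correlations(ddt$ddt, seq_along(sel))
  pr <- correlation_proportions(pc)
  cond <- manifest$condition[k]
  sets_by_cond[[cond]] <- c(sets_by_cond[[cond]], list(pc))
  props <- rbind(props, data.frame(
    trial_id = manifest$trial_id[k], condition = cond,
    neg_prop = pr$neg_prop, pos_prop = pr$pos_prop, n_pairs = pr$n_pairs))
}
write.csv(props, "results/correlation_proportions.csv", row.names = FALSE)

hists <- NULL
for (cond in names(sets_by_cond)) {
  h <- pooled_correlation_histogram(sets_by_cond[[cond]], bins = 40)
  hists <- rbind(hists, data.frame(condition = cond, r_mid = h$mids,
                                   prob = h$prob))
}
write.csv(hists, "results/correlation_histograms.csv", row.names = FALSE)
cat("mean correlation proportions by condition:\n")
print(aggregate(cbind(neg_prop, pos_prop) ~ condition, props, mean))
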
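#!/usr/bin/env Rscript
# State-space organization and global quiescence: PCA explained variance,
# trajectory angular-change histograms, recurrence maps (summary stats),
# per-frame quiescence profiles and 700-frame subset extraction.

library(wormdyn)

manifest <- read.csv("results/cohort_manifest.csv")
rows <- NULL
angles_by_cond <- list()
profiles_by_cond <- list()
for (k in seq_len(nrow(manifest))) {
  tr <- load_traces(manifest$path[k])
  d <- normalize_dff(tr)
  traj <- run_pca(d, k = 3)
  ang <- angular_changes(traj, window_s = 3)
  qp <- quiescence_profile(d)
  cond <- manifest$condition[k]
  angles_by_cond[[cond]] <- c(angles_by_cond[[cond]], list(ang))
  profiles_by_cond[[cond]] <- c(profiles_by_cond[[cond]], list(qp))
  a <- ang$angles[!is.na(ang$angles)]
  rows <- rbind(rows, data.frame(
    trial_id = manifest$trial_id[k], condition = cond,
    ev1 = traj$explained_var[1], ev2 = traj$explained_var[2],
    ev3 = traj$explained_var[3],
    angle_low_bin_mass = mean(a < 30),
    time_in_quiescence = qp$time_in_quiescence))
}
write.csv(rows, "results/states_quiescence.csv", row.names = FALSE)

hists <- NULL
for (cond in names(angles_by_cond)) {
  h <- angle_histogram(angles_by_cond[[cond]], bins = 18)
  hists <- rbind(hists, data.frame(condition = cond, angle_mid = h$mids,
                                   prob = h$prob))
  hq <- quiescent_fraction_distribution(profiles_by_cond[[cond]], bins = 20)
  hists_q <- data.frame(condition = cond, fraction_mid = hq$mids,
                        prob = hq$prob)
  write.csv(hists_q, sprintf("results/quiescent_fraction_hist_%s.csv", cond),
            row.names = FALSE)
}
write.csv(hists, "results/angle_histograms.csv", row.names = FALSE)

# 700-frame quiescent vs quiescence-free subsets from the aged cohort
subsets <- NULL
for (k in which(manifest$condition == "day9")) {
  tr <- load_traces(manifest$path[k])
  qp <- quiescence_profile(normalize_dff(tr))
  for (want in c(TRUE, FALSE)) {
    seg <- extract_subset(tr, qp, 700, want_quiescence = want)
    if (is.null(seg)) next
    m <- run_worm_metrics(seg, "multi")
    subsets <- rbind(subsets, data.frame(
      source = manifest$trial_id[k], window = seg$trial_id,
      quiescent_subset = want, neg_prop = m$neg_prop, pos_prop = m$pos_prop,
      spectral_edge_40 = m$spectral_edge_40))
  }
}
if (!is.null(subsets)) {
  write.csv(subsets, "results/quiescence_subsets.csv", row.names = FALSE)
  cat("subset positive-correlation proportions (quiescent vs clean):\n")
  print(aggregate(pos_prop ~ quiescent_subset, subsets, mean))
}
cat("per-condition summary:\n")
print(aggregate(cbind(ev1, angle_low_bin_mass, time_in_quiescence) ~ condition,
                rows, mean))
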
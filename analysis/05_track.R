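#!/usr/bin/env Rscript
# Register neurons across habituation -> CS2-CS1 -> test by footprint
# centroids (the shock day is excluded from tracking), then follow each
# tracked neuron's CS2 response category across phases: trajectories,
# the habituation-vs-test transition matrix, and group-wise mean AUC for
# neurons grouped by their habituation category.

source("analysis/00_config.R")

exp <- get_experiment()
phases <- c("habituation", "cs2_cs1", "test")

feats <- lapply(phases, function(ph) {
  c <- exp$sessions[[ph]]$centroids
  list(neuron_ids = c$neuron_id,
       centroids = as.matrix(c[, c("x_um", "y_um")]))
})
maps <- Map(function(a, b)
  match_sessions(a, b, threshold = 0.5, weights = c(spatial = 1, trace = 0)),
  feats[-3], feats[-1])
tracked <- chain_maps(maps)

cls <- lapply(phases, function(ph) {
  cl <- utils::read.csv(out_path(sprintf("classification_%s.csv", ph)))
  cl$category <- factor(cl$category,
                        levels = c("increased", "no_change", "decreased",
                                   "degenerate"))
  cl
})
names(cls) <- phases
trk <- track_categories(tracked, cls)

utils::write.csv(trk$trajectories, out_path("trajectories.csv"),
                 row.names = FALSE)
utils::write.csv(as.data.frame(trk$transition),
                 out_path("transition_matrix.csv"), row.names = FALSE)
utils::write.csv(trk$group_auc, out_path("group_auc.csv"),
                 row.names = FALSE)

# how many true correspondences did centroid matching recover?
truth_common <- rownames(exp$presence)[rowSums(exp$presence[, phases]) == 3]
cat(sprintf("tracked %d neurons across %d phases (%d true triple-presences)\n",
            trk$n_tracked, length(phases), length(truth_common)))
hab_counts <- rowSums(trk$transition)
for (g in names(hab_counts)[hab_counts > 0]) {
  cat(sprintf("  habituation '%s': %d neurons (%.1f%%)\n", g,
              hab_counts[[g]], percent1(hab_counts[[g]], trk$n_tracked)))
}
cat("habituation -> test transitions:\n")
print(trk$transition)
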
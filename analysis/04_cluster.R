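#!/usr/bin/env Rscript
# Cluster test-day z-scored peri-event traces (-10..+20 s) with K-means
# at k = 5, validate the choice of k with a silhouette scan over 2..8,
# and export labels, centroid traces and the silhouette curve.

source("analysis/00_config.R")

exp <- get_experiment()
ses <- exp$sessions$test
dff <- delta_f_over_f(ses$trace)
zavg <- trial_average(z_score(dff, ses$events, "CS2", window_spec(10, 20)))
zavg <- zavg[stats::complete.cases(zavg), , drop = FALSE]

res <- cluster_traces(zavg, k = 5, seed = STUDY_SEED)
sel <- select_k(zavg, 2:8, seed = STUDY_SEED)

utils::write.csv(data.frame(neuron_id = names(res$labels),
                            cluster = res$labels),
                 out_path("clusters_test.csv"), row.names = FALSE)
cent <- data.frame(time_rel = seq(-10, 20, by = 0.1), t(res$centroids))
names(cent)[-1] <- paste0("cluster_", seq_len(res$k))
utils::write.csv(cent, out_path("cluster_centroids_test.csv"),
                 row.names = FALSE)
utils::write.csv(sel$curve, out_path("silhouette_curve.csv"),
                 row.names = FALSE)

cat(sprintf("k = 5 cluster sizes: %s (%s%%), mean silhouette %.3f\n",
            paste(res$sizes, collapse = ", "),
            paste(res$percent, collapse = ", "), res$silhouette))
cat(sprintf("silhouette scan over k = 2..8 chooses k = %d\n",
            sel$chosen_k))
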
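#' Run the full SOC analysis pipeline on a synthetic experiment
#'
#' Orchestrates every stage from one configuration: simulate all phases
#' (traces, events, behavior), dF/F-normalize, align and z-score to each
#' phase's primary cue, classify neurons by the AUC-ratio rule, cluster
#' the test-phase responses (k = 5 plus a silhouette scan), register
#' neurons longitudinally across habituation / CS2-CS1 / test (the
#' shock day is excluded from tracking, as in the study), compare
#' within-state maximum pairwise correlations (baseline vs tone) by
#' Cohen's d, quantify freezing and the second-order memory-strength
#' ratio, and write every stage table as CSV plus a JSON run report with
#' counts and file checksums. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A [sim_config()]; `seed` overrides its seed.
#' @param outdir Output directory (created if missing).
#' @param seed Optional integer seed override.
#' @param k Number of clusters for the test-phase archetypes.
#' @param k_range Silhouette scan range.
#' @param registration_threshold Minimum accepted match score.
#' @return The run report (list), invisibly; all artifacts under
#'   `outdir`.
#' @export
run_soc_pipeline <- function(config = sim_config(), outdir, seed = NULL,
                             k = 5, k_range = 2:8,
                             registration_threshold = 0.5) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(
    utils::packageVersion("soccal")), seed = config$seed, stages = list())
  files <- character(0)
  put <- function(df, name, writer = utils::write.csv) {
    path <- file.path(outdir, name)
    writer(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  exp <- simulate_experiment(config)
  cue <- c(habituation = "CS2", cs1_us = "CS1", cs2_cs1 = "CS2",
           test = "CS2")
  phases <- names(exp$sessions)

  classifications <- list()
  zavg <- list()
  for (ph in phases) {
    ses <- exp$sessions[[ph]]
    write_trace_csv(ses$trace, file.path(outdir, paste0("trace_", ph, ".csv")))
    files <- c(files, file.path(outdir, paste0("trace_", ph, ".csv")))
    put(ses$events, paste0("events_", ph, ".csv"))
    write_motion_csv(ses$motion, file.path(outdir, paste0("motion_", ph, ".csv")))
    files <- c(files, file.path(outdir, paste0("motion_", ph, ".csv")))

    dff <- delta_f_over_f(ses$trace)
    tensor <- align_trials(dff, ses$events, cue[[ph]],
                           window_spec(10, 20))
    ztensor <- z_score(dff, ses$events, cue[[ph]], window_spec(10, 20))
    zavg[[ph]] <- trial_average(ztensor)
    auc <- peri_auc(tensor)
    cl <- classify_responses(auc)
    classifications[[ph]] <- cl
    put(cl, paste0("classification_", ph, ".csv"))
    put(summarize_population(cl), paste0("summary_", ph, ".csv"))
    report$stages[[ph]] <- list(
      n_neurons = nrow(ses$trace$values),
      n_events = nrow(ses$events),
      n_trials_used = nrow(tensor$trials),
      n_trials_excluded = nrow(tensor$excluded),
      n_degenerate = nrow(ztensor$degenerate))
  }

  keep <- stats::complete.cases(zavg$test)
  sel <- select_k(zavg$test[keep, , drop = FALSE], k_range = k_range,
                  seed = config$seed)
  clus <- if (sel$chosen_k == k) sel$result else
    cluster_traces(zavg$test[keep, , drop = FALSE], k = k,
                   seed = config$seed)
  put(data.frame(neuron_id = names(clus$labels), cluster = clus$labels),
      "clusters_test.csv")
  put(sel$curve, "silhouette_curve.csv")
  report$stages$clustering <- list(
    k = clus$k, chosen_k = sel$chosen_k, sizes = clus$sizes,
    silhouette = clus$silhouette)

  track_phases <- intersect(c("habituation", "cs2_cs1", "test"), phases)
  feats <- lapply(track_phases, function(ph) {
    ses <- exp$sessions[[ph]]
    list(neuron_ids = ses$centroids$neuron_id,
         centroids = as.matrix(ses$centroids[, c("x_um", "y_um")]))
  })
  maps <- Map(function(a, b) match_sessions(
    a, b, threshold = registration_threshold,
    weights = c(spatial = 1, trace = 0)),
    feats[-length(feats)], feats[-1L])
  tracked <- chain_maps(maps)
  trk <- track_categories(tracked, classifications[track_phases])
  put(trk$trajectories, "trajectories.csv")
  put(as.data.frame(trk$transition), "transition_matrix.csv")
  put(trk$group_auc, "group_auc.csv")
  report$stages$longitudinal <- list(
    n_tracked = trk$n_tracked, n_dropped = trk$n_dropped,
    pairs_per_map = vapply(maps, nrow, integer(1)))

  dff_test <- delta_f_over_f(exp$sessions$test$trace)
  comp <- compare_state_correlations(
    dff_test,
    state_windows(exp$sessions$test$events, "baseline"),
    state_windows(exp$sessions$test$events, "CS2"),
    states = c("baseline", "tone"))
  put(comp$per_neuron, "state_correlations.csv")
  report$stages$correlation <- list(d = comp$d, n = comp$n)

  fz <- list()
  for (ph in phases) {
    fz[[ph]] <- freezing_percent(exp$sessions[[ph]]$motion,
                                 exp$sessions[[ph]]$events,
                                 mouse_id = "sim1")
    put(fz[[ph]], paste0("freezing_", ph, ".csv"))
  }
  ms <- if (all(c("test", "cs2_cs1") %in% phases)) {
    memory_strength(
      fz$test[fz$test$event_label == "CS2", ],
      fz$cs2_cs1[fz$cs2_cs1$event_label == "CS1", ])
  } else NULL
  if (!is.null(ms)) {
    put(ms$per_mouse, "memory_strength.csv")
    report$stages$behavior <- list(memory_strength_percent = ms$mean)
  }

  report$files <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
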
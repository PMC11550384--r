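#' Match neurons across two imaging sessions
#'
#' Greedy one-to-one matching on a similarity score in `[0, 1]`, with the
#' same 0.5 acceptance threshold the study used for longitudinal
#' registration. Per-neuron features are footprint centroids and/or a
#' reference (session-mean peri-event) trace:
#' \itemize{
#'   \item centroid similarity: `exp(-(d / centroid_scale)^2)` of the
#'     Euclidean centroid distance `d`;
#'   \item trace similarity: Pearson correlation of the reference traces.
#' }
#' When both components are present the score is their weighted mean with
#' the correlation rescaled to `[0, 1]` as `(1 + r) / 2`, so an
#' uninformative correlation (r near 0) is neutral rather than vetoing a
#' spatially obvious match; with trace-only features the score is the raw
#' correlation, preserving "minimum correlation 0.5" semantics. Matching
#' is deterministic (ties broken by neuron id, symmetrically in the two
#' sessions) and symmetric: `match_sessions(a, b)` pairs equal
#' `match_sessions(b, a)`.
#'
#' @param a,b Session feature lists: `neuron_ids` (character), optional
#'   `centroids` (n x 2 matrix, micrometres), optional `ref_traces`
#'   (n x time matrix).
#' @param threshold Minimum accepted score (default 0.5).
#' @param weights Named weights `c(spatial = , trace = )` for the two
#'   components; renormalized over the components actually available.
#' @param centroid_scale Length scale of the spatial score (micrometres).
#' @return A `registration_map`: data frame `id_a`, `id_b`, `score`, with
#'   attributes `unmatched_a`, `unmatched_b`.
#' @export
match_sessions <- function(a, b, threshold = 0.5,
                           weights = c(spatial = 0.5, trace = 0.5),
                           centroid_scale = 10) {
  if (!length(a$neuron_ids) || !length(b$neuron_ids))
    stop("empty session: both sessions need at least one neuron")
  na <- length(a$neuron_ids); nb <- length(b$neuron_ids)
  comps <- list()
  if (!is.null(a$centroids) && !is.null(b$centroids)) {
    d2 <- outer(a$centroids[, 1L], b$centroids[, 1L], "-")^2 +
      outer(a$centroids[, 2L], b$centroids[, 2L], "-")^2
    comps$spatial <- exp(-d2 / centroid_scale^2)
  }
  if (!is.null(a$ref_traces) && !is.null(b$ref_traces)) {
    r <- stats::cor(t(a$ref_traces), t(b$ref_traces))
    comps$trace <- if (is.null(comps$spatial)) r else (1 + r) / 2
  }
  if (!length(comps)) stop("sessions share no feature (centroids or traces)")
  w <- weights[names(comps)]
  w <- w / sum(w)
  score <- Reduce(`+`, Map(`*`, comps, w))

  cand <- which(score >= threshold, arr.ind = TRUE)
  pairs <- data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cand)) {
    sc <- score[cand]
    ida <- a$neuron_ids[cand[, 1L]]
    idb <- b$neuron_ids[cand[, 2L]]
    ord <- order(-sc, pmin(ida, idb), pmax(ida, idb))
    used_a <- logical(na); used_b <- logical(nb)
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          id_a = a$neuron_ids[i], id_b = b$neuron_ids[j],
          score = score[i, j], stringsAsFactors = FALSE))
      }
    }
    pairs <- pairs[order(pairs$id_a), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  attr(pairs, "unmatched_a") <- setdiff(a$neuron_ids, pairs$id_a)
  attr(pairs, "unmatched_b") <- setdiff(b$neuron_ids, pairs$id_b)
  class(pairs) <- c("registration_map", "data.frame")
  pairs
}

#' Chain registration maps across an ordered series of sessions
#'
#' Composes pairwise maps (session 1 -> 2 -> ... -> S) into the set of
#' neurons tracked across every session.
#'
#' @param maps List of `registration_map`s for consecutive session pairs.
#' @return Data frame with one id column per session (`s1..sS`), one row
#'   per fully tracked neuron.
#' @export
chain_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  out <- data.frame(s1 = maps[[1L]]$id_a, s2 = maps[[1L]]$id_b,
                    stringsAsFactors = FALSE)
  for (k in seq_along(maps)[-1L]) {
    m <- maps[[k]]
    idx <- match(out[[ncol(out)]], m$id_a)
    out <- out[!is.na(idx), , drop = FALSE]
    out[[paste0("s", k + 1L)]] <- m$id_b[idx[!is.na(idx)]]
  }
  rownames(out) <- NULL
  out
}

#' Track response categories of registered neurons across phases
#'
#' Restricts per-phase classifications to the neurons tracked through all
#' phases and summarizes how categories change from the first phase to
#' the last: per-neuron category trajectories, the first-vs-last-phase
#' transition matrix, and group-wise mean AUC per phase for neurons
#' grouped by their first-phase (habituation) category.
#'
#' @param tracked Data frame from [chain_maps()] (or a single
#'   `registration_map`), one id column per phase in order.
#' @param classifications Named list (one per phase, same order as the id
#'   columns) of [classify_responses()] tables.
#' @return List `trajectories` (data frame: tracked id per phase +
#'   `category_<phase>` + `auc_post_<phase>`), `transition` (first-phase x
#'   last-phase category count matrix), `group_auc` (data frame: first-
#'   phase category, phase, mean AUC, sem, n), `n_tracked`, `n_dropped`.
#' @export
track_categories <- function(tracked, classifications) {
  if (inherits(tracked, "registration_map"))
    tracked <- data.frame(s1 = tracked$id_a, s2 = tracked$id_b,
                          stringsAsFactors = FALSE)
  phases <- names(classifications)
  stopifnot(length(phases) == ncol(tracked))
  n0 <- nrow(tracked)
  traj <- tracked
  names(traj) <- paste0("id_", phases)
  keep <- rep(TRUE, n0)
  for (k in seq_along(phases)) {
    cl <- classifications[[k]]
    idx <- match(tracked[[k]], cl$neuron_id)
    keep <- keep & !is.na(idx)
    traj[[paste0("category_", phases[k])]] <-
      as.character(cl$category)[idx]
    traj[[paste0("auc_post_", phases[k])]] <- cl$auc_post[idx]
  }
  traj <- traj[keep, , drop = FALSE]
  rownames(traj) <- NULL
  lev <- c("increased", "no_change", "decreased", "degenerate")
  first <- factor(traj[[paste0("category_", phases[1L])]], levels = lev)
  last <- factor(traj[[paste0("category_", phases[length(phases)])]],
                 levels = lev)
  transition <- table(first, last, dnn = c(phases[1L],
                                           phases[length(phases)]))
  group_auc <- do.call(rbind, lapply(levels(first), function(g) {
    rows <- which(first == g)
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(phases, function(ph) {
      v <- traj[[paste0("auc_post_", ph)]][rows]
      data.frame(group = g, phase = ph, mean_auc = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(trajectories = traj, transition = transition,
       group_auc = group_auc, n_tracked = nrow(traj),
       n_dropped = n0 - nrow(traj))
}
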
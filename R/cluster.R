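#' K-means clustering of peri-event response archetypes
#'
#' Clusters per-neuron trial-averaged z-scored traces (typically the
#' -10..+20 s window around the cue) with Euclidean K-means, many random
#' restarts and a fixed seed, mirroring the response-type analysis of the
#' imaging study (k = 5 by default there).
#'
#' @param avg Neuron x time matrix from [trial_average()] of a z-scored
#'   tensor.
#' @param k Number of clusters (2 <= k < n_neurons).
#' @param seed Integer seed for the restarts.
#' @param nstart Random restarts; best within-cluster sum of squares kept.
#' @return A `cluster_result`: list with `labels` (named integer vector in
#'   `1..k`), `centroids` (k x time matrix), `sizes`, `percent`
#'   (one-decimal, half-up), `silhouette` (mean silhouette width), `k`,
#'   `seed`.
#' @export
cluster_traces <- function(avg, k = 5, seed = 1L, nstart = 50L) {
  stopifnot(is.matrix(avg))
  n <- nrow(avg)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n_neurons")
  if (anyNA(avg)) stop("traces must be finite (drop degenerate neurons)")
  if (all(apply(avg, 2L, function(col) max(col) - min(col)) < 1e-12))
    stop("all traces identical: clustering degenerate, silhouette undefined")
  labels <- with_seed(seed, {
    km <- stats::kmeans(avg, centers = k, nstart = nstart, iter.max = 100L)
    km$cluster
  })
  km_cent <- t(vapply(seq_len(k), function(g)
    colMeans(avg[labels == g, , drop = FALSE]), numeric(ncol(avg))))
  sil <- cluster::silhouette(labels, stats::dist(avg))
  sizes <- as.integer(table(factor(labels, levels = seq_len(k))))
  structure(list(
    labels = stats::setNames(labels, rownames(avg)),
    centroids = km_cent, sizes = sizes,
    percent = percent1(sizes, n),
    silhouette = mean(sil[, "sil_width"]),
    time_rel = attr(avg, "time_rel"), k = k, seed = seed),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k=%d, sizes: %s (%s%%), mean silhouette %.3f\n",
              x$k, paste(x$sizes, collapse = ", "),
              paste(x$percent, collapse = ", "), x$silhouette))
  invisible(x)
}

#' Silhouette-based selection of the number of clusters
#'
#' Runs [cluster_traces()] over a range of k and picks the k with the
#' largest mean silhouette width (smallest k on ties). A flat silhouette
#' curve never exceeding 0.2 triggers a "no cluster structure" warning.
#'
#' @inheritParams cluster_traces
#' @param k_range Integer vector of candidate k (all in
#'   `[2, n_neurons - 1]`).
#' @return List `chosen_k`, `curve` (data frame `k`, `silhouette`),
#'   `result` (the `cluster_result` at the chosen k).
#' @export
select_k <- function(avg, k_range = 2:8, seed = 1L, nstart = 50L) {
  if (!length(k_range)) stop("empty k range")
  stopifnot(all(k_range >= 2), all(k_range < nrow(avg)))
  fits <- lapply(k_range, function(k)
    cluster_traces(avg, k = k, seed = seed, nstart = nstart))
  sil <- vapply(fits, `[[`, numeric(1), "silhouette")
  best <- which.max(sil) # which.max returns the first (smallest k) on ties
  if (max(sil) <= 0.2)
    warning("no cluster structure: mean silhouette <= 0.2 for all k")
  list(chosen_k = k_range[best],
       curve = data.frame(k = k_range, silhouette = sil),
       result = fits[[best]])
}
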
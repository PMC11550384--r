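#' Build state windows from a session
#'
#' Convenience constructor of the time intervals defining a behavioral
#' state: the pre-session `baseline` (default the 5 min before the first
#' event) or all cue windows of one label.
#'
#' @param events An [event_table()].
#' @param state `"baseline"` or an event label present in `events`.
#' @param baseline_s Length of the baseline state before the first event.
#' @return Matrix with columns `start`, `end` (seconds), one interval per
#'   row.
#' @export
state_windows <- function(events, state, baseline_s = 300) {
  if (state == "baseline") {
    t0 <- min(events$onset_s)
    cbind(start = max(0, t0 - baseline_s), end = t0)
  } else {
    ev <- events[events$event_label == state, , drop = FALSE]
    if (!nrow(ev)) stop("no events labelled '", state, "'")
    cbind(start = ev$onset_s, end = ev$onset_s + ev$duration_s)
  }
}

#' Maximum pairwise correlation per neuron within a state
#'
#' Concatenates the samples of all intervals of a state, computes the
#' Pearson correlation of every neuron pair on those samples (zero lag),
#' and reports each neuron's maximum correlation over all partners.
#' Neurons with zero variance within the state are excluded and counted.
#'
#' @param trace A (normalized) [trace_matrix()].
#' @param windows Interval matrix from [state_windows()] (columns
#'   `start`, `end`; intervals must not overlap and must hold >= 2
#'   samples in total).
#' @return Data frame `neuron_id`, `max_r` with attribute `excluded`
#'   (ids of zero-variance neurons).
#' @export
max_pairwise_corr <- function(trace, windows) {
  stopifnot(inherits(trace, "trace_matrix"), nrow(trace$values) >= 2L)
  windows <- windows[order(windows[, "start"]), , drop = FALSE]
  if (nrow(windows) > 1L &&
      any(windows[-1L, "start"] < windows[-nrow(windows), "end"] - 1e-9))
    stop("state intervals overlap")
  idx <- unlist(lapply(seq_len(nrow(windows)), function(j)
    which(trace$times >= windows[j, "start"] - 1e-9 &
            trace$times < windows[j, "end"] - 1e-9)))
  if (length(idx) < 2L) stop("state windows hold fewer than 2 samples")
  x <- trace$values[, idx, drop = FALSE]
  v <- apply(x, 1L, stats::var)
  excluded <- trace$neuron_ids[v == 0]
  x <- x[v > 0, , drop = FALSE]
  if (nrow(x) < 2L) stop("fewer than 2 neurons with variance in the state")
  r <- stats::cor(t(x))
  diag(r) <- -Inf
  out <- data.frame(neuron_id = rownames(x),
                    max_r = apply(r, 1L, max),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Cohen's d between two groups of values
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' usual pooled SD (N - 1 weighting). Antisymmetric in its arguments.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return Cohen's d (positive when `a` has the larger mean).
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("pooled SD is zero: Cohen's d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Compare per-neuron maximum correlations between two states
#'
#' Runs [max_pairwise_corr()] in each state and summarizes the difference
#' with Cohen's d (state a minus state b).
#'
#' @param trace A (normalized) [trace_matrix()].
#' @param windows_a,windows_b Interval matrices from [state_windows()].
#' @param states Length-2 labels for reporting.
#' @return List `per_neuron` (long data frame: `neuron_id`, `state`,
#'   `max_r`), `d` (Cohen's d), `n` (group sizes).
#' @export
compare_state_correlations <- function(trace, windows_a, windows_b,
                                       states = c("a", "b")) {
  ra <- max_pairwise_corr(trace, windows_a)
  rb <- max_pairwise_corr(trace, windows_b)
  per <- rbind(
    data.frame(neuron_id = ra$neuron_id, state = states[1L],
               max_r = ra$max_r, stringsAsFactors = FALSE),
    data.frame(neuron_id = rb$neuron_id, state = states[2L],
               max_r = rb$max_r, stringsAsFactors = FALSE))
  list(per_neuron = per, d = cohens_d(ra$max_r, rb$max_r),
       n = c(nrow(ra), nrow(rb)))
}
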
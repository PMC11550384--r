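#' Trial-averaged peri-event traces
#'
#' Pointwise mean across trials per neuron. Degenerate (all-`NA`) trials
#' are ignored.
#'
#' @param tensor A `peri_event_tensor` from [align_trials()] or
#'   [z_score()].
#' @return Numeric matrix (neurons x time) with the relative time axis in
#'   attribute `time_rel`.
#' @export
trial_average <- function(tensor) {
  stopifnot(inherits(tensor, "peri_event_tensor"))
  out <- apply(tensor$values, c(1L, 3L), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  attr(out, "time_rel") <- tensor$time_rel
  attr(out, "event_label") <- tensor$event_label
  out
}

#' Population-average trace with SEM
#'
#' @param avg Neuron x time matrix from [trial_average()].
#' @return Data frame `time_rel`, `mean`, `sem`, `n`.
#' @export
population_average <- function(avg) {
  n <- colSums(!is.na(avg))
  data.frame(time_rel = attr(avg, "time_rel"),
             mean = colMeans(avg, na.rm = TRUE),
             sem = apply(avg, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1)),
             n = n)
}

#' Pre/post AUC per neuron
#'
#' Trapezoidal area under the trial-averaged peri-event trace over the
#' baseline window (default -10..0 s), the response window (0..10 s) and
#' the post-cue window (10..20 s, reported as `auc_late` to support
#' sustained-activity analyses). The ratio `auc_post / auc_pre` feeds the
#' responsive-neuron classification.
#'
#' @param x A `peri_event_tensor` or a neuron x time matrix from
#'   [trial_average()] (with `time_rel` attribute).
#' @param pre,post,late Length-2 numeric windows in relative seconds;
#'   `late = NULL` suppresses the late window.
#' @return Data frame `neuron_id`, `event_label`, `auc_pre`, `auc_post`,
#'   `auc_late`, `ratio`, with attribute `pre_window_s` (baseline window
#'   length, used by [classify_responses()]).
#' @export
peri_auc <- function(x, pre = c(-10, 0), post = c(0, 10),
                     late = c(10, 20)) {
  if (inherits(x, "peri_event_tensor")) {
    avg <- trial_average(x)
  } else {
    avg <- x
    stopifnot(!is.null(attr(avg, "time_rel")))
  }
  tt <- attr(avg, "time_rel")
  win_auc <- function(w) {
    if (is.null(w)) return(rep(NA_real_, nrow(avg)))
    idx <- which(tt >= w[1L] - 1e-9 & tt <= w[2L] + 1e-9)
    if (length(idx) < 2L)
      stop("AUC window [", w[1L], ", ", w[2L],
           "] lies outside the tensor range [", min(tt), ", ", max(tt), "]")
    apply(avg[, idx, drop = FALSE], 1L,
          function(v) pracma::trapz(tt[idx], v))
  }
  auc_pre <- win_auc(pre)
  auc_post <- win_auc(post)
  out <- data.frame(
    neuron_id = rownames(avg), event_label = attr(avg, "event_label"),
    auc_pre = auc_pre, auc_post = auc_post, auc_late = win_auc(late),
    ratio = auc_post / auc_pre, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pre_window_s") <- diff(pre)
  out
}

#' Per-trial AUC table
#'
#' Same windows as [peri_auc()] but computed per trial, for trial-course
#' analyses (e.g. early vs late conditioning trials).
#'
#' @inheritParams peri_auc
#' @param tensor A `peri_event_tensor`.
#' @return Long data frame `neuron_id`, `trial`, `auc_pre`, `auc_post`.
#' @export
trial_auc <- function(tensor, pre = c(-10, 0), post = c(0, 10)) {
  stopifnot(inherits(tensor, "peri_event_tensor"))
  tt <- tensor$time_rel
  ipre <- which(tt >= pre[1L] - 1e-9 & tt <= pre[2L] + 1e-9)
  ipost <- which(tt >= post[1L] - 1e-9 & tt <= post[2L] + 1e-9)
  dims <- dim(tensor$values)
  grid <- expand.grid(neuron = seq_len(dims[1L]), trial = seq_len(dims[2L]))
  data.frame(
    neuron_id = tensor$neuron_ids[grid$neuron], trial = grid$trial,
    auc_pre = mapply(function(i, j)
      pracma::trapz(tt[ipre], tensor$values[i, j, ipre]),
      grid$neuron, grid$trial),
    auc_post = mapply(function(i, j)
      pracma::trapz(tt[ipost], tensor$values[i, j, ipost]),
      grid$neuron, grid$trial),
    stringsAsFactors = FALSE)
}
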
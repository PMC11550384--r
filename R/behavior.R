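#' Freezing percent per cue window
#'
#' Classifies every motion sample as frozen when its magnitude is below
#' `threshold` for at least `min_bout_s` contiguous seconds (run lengths
#' measured on the whole trace, so bouts spanning a window edge count),
#' then reports the percent of frozen time inside each cue window of the
#' 10 s cues, plus the post-cue (offset to offset + `post_s`) percent.
#' `min_bout_s = 0` reproduces pure thresholding, the mode used when
#' validating recovery of planted freeze fractions.
#'
#' @param motion Data frame `time_s`, `motion` (uniform sampling,
#'   non-negative magnitudes).
#' @param events An [event_table()].
#' @param labels Event labels to score (default all except `"US"`).
#' @param threshold Motion magnitude below which a frame counts as still.
#' @param min_bout_s Minimum duration of a still run to count as freezing.
#' @param mouse_id Identifier copied into the output.
#' @param post_s Length of the optional post-cue window (0 disables).
#' @return Data frame `mouse_id`, `event_label`, `trial_index`,
#'   `freeze_percent`, `post_freeze_percent`.
#' @export
freezing_percent <- function(motion, events, labels = NULL,
                             threshold = 0.5, min_bout_s = 1,
                             mouse_id = "m1", post_s = 10) {
  stopifnot(threshold >= 0, min_bout_s >= 0)
  times <- motion$time_s
  dt <- times[2L] - times[1L]
  still <- motion$motion < threshold
  frozen <- still
  if (min_bout_s > 0) {
    need <- max(1L, round(min_bout_s / dt))
    runs <- rle(still)
    runs$values <- runs$values & runs$lengths >= need
    frozen <- inverse.rle(runs)
  }
  if (is.null(labels)) labels <- setdiff(unique(events$event_label), "US")
  ev <- events[events$event_label %in% labels, , drop = FALSE]
  pct_in <- function(t0, t1) {
    idx <- which(times >= t0 - 1e-9 & times < t1 - 1e-9)
    if (!length(idx)) stop("empty scoring window [", t0, ", ", t1, ")")
    100 * mean(frozen[idx])
  }
  data.frame(
    mouse_id = mouse_id,
    event_label = ev$event_label,
    trial_index = ev$trial_index,
    freeze_percent = mapply(pct_in, ev$onset_s,
                            ev$onset_s + ev$duration_s),
    post_freeze_percent = if (post_s > 0)
      mapply(pct_in, ev$onset_s + ev$duration_s,
             pmin(ev$onset_s + ev$duration_s + post_s, max(times)))
    else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Second-order memory-strength ratio
#'
#' Per mouse: mean test-phase CS2 freezing divided by the reference CS1
#' freezing (from the CS2-CS1 pairing session by convention), times 100.
#' Mice with zero CS1 reference freezing are excluded with a warning.
#'
#' @param cs2_records Freezing records ([freezing_percent()] rows) for
#'   the test-phase CS2 trials, possibly several mice.
#' @param cs1_records Reference freezing records for CS1.
#' @return List `per_mouse` (data frame `mouse_id`, `cs2_percent`,
#'   `cs1_percent`, `ratio_percent`), `mean` and `sem` of the ratio.
#' @export
memory_strength <- function(cs2_records, cs1_records) {
  mice <- intersect(unique(cs2_records$mouse_id),
                    unique(cs1_records$mouse_id))
  if (!length(mice)) stop("no mouse has both CS2 and CS1 records")
  per <- do.call(rbind, lapply(mice, function(m) {
    cs2 <- mean(cs2_records$freeze_percent[cs2_records$mouse_id == m])
    cs1 <- mean(cs1_records$freeze_percent[cs1_records$mouse_id == m])
    data.frame(mouse_id = m, cs2_percent = cs2, cs1_percent = cs1,
               ratio_percent = if (cs1 > 0) 100 * cs2 / cs1 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (anyNA(per$ratio_percent)) {
    warning(sum(is.na(per$ratio_percent)),
            " mouse/mice with zero CS1 reference freezing excluded")
    per <- per[!is.na(per$ratio_percent), , drop = FALSE]
  }
  list(per_mouse = per, mean = mean(per$ratio_percent),
       sem = if (nrow(per) > 1L)
         stats::sd(per$ratio_percent) / sqrt(nrow(per)) else NA_real_)
}

#' Extinction curve and decay summary
#'
#' Trial-ordered group means of freezing percent over an extinction
#' series, with the decay summarized by the rate of an exponential
#' `y_t = a * exp(-rate * (t - 1))` fitted by least squares on
#' `log(pmax(y, floor))`. A constant curve has rate 0; an all-zero curve
#' has no defined rate and is flagged.
#'
#' @param records Freezing records across >= 2 trials of one cue
#'   (columns `trial_index`, `freeze_percent`; several mice are averaged
#'   per trial).
#' @param floor Positive floor applied before taking logs (percent).
#' @return List `per_trial` (data frame `trial_index`, `mean_percent`,
#'   `sem`, `n`), `decay_rate` (per trial; `NA` when undefined),
#'   `defined` (logical).
#' @export
extinction_curve <- function(records, floor = 0.5) {
  stopifnot(floor > 0)
  trials <- sort(unique(records$trial_index))
  if (length(trials) < 2L) stop("extinction needs >= 2 trials")
  per <- do.call(rbind, lapply(trials, function(tr) {
    v <- records$freeze_percent[records$trial_index == tr]
    data.frame(trial_index = tr, mean_percent = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  if (all(per$mean_percent == 0)) {
    return(list(per_trial = per, decay_rate = NA_real_, defined = FALSE))
  }
  fit <- stats::lm(log(pmax(mean_percent, floor)) ~ trial_index, data = per)
  list(per_trial = per,
       decay_rate = -unname(stats::coef(fit)[2L]),
       defined = TRUE)
}
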
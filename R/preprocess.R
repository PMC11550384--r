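#' Whole-trace dF/F normalization
#'
#' Converts raw fluorescence to fractional change about the whole-trace
#' mean: per neuron, `(F - mean(F)) / mean(F)`. Each output row therefore
#' has zero mean, and the transform is invariant to positive rescaling of
#' the raw signal.
#'
#' @param trace A raw [trace_matrix()] with strictly positive per-neuron
#'   means.
#' @return A [trace_matrix()] with `normalized = TRUE`.
#' @export
delta_f_over_f <- function(trace) {
  stopifnot(inherits(trace, "trace_matrix"))
  m <- rowMeans(trace$values)
  bad <- which(m <= 0)
  if (length(bad))
    stop("non-positive mean fluorescence for neuron(s): ",
         paste(trace$neuron_ids[bad], collapse = ", "))
  out <- sweep(sweep(trace$values, 1, m, "-"), 1, m, "/")
  trace_matrix(out, trace$times, trace$neuron_ids,
               sampling_rate_hz = trace$sampling_rate_hz,
               phase = trace$phase, normalized = TRUE)
}

#' Peri-event window specification
#'
#' @param pre_s Baseline length before event onset (s, > 0); the baseline
#'   segment is the half-open window `[-pre_s, 0)`.
#' @param post_s Response length after onset (s, > 0); response samples
#'   cover `[0, post_s]`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(pre_s = 10, post_s = 20) {
  stopifnot(pre_s > 0, post_s > 0)
  structure(list(pre_s = pre_s, post_s = post_s), class = "window_spec")
}

#' Align a trace matrix to events
#'
#' Extracts one `[-pre_s, +post_s]` slice per qualifying event of the
#' requested label. Event onset maps to the first sample with
#' `t >= onset`; trials whose window does not fit inside the session are
#' excluded and enumerated, never padded.
#'
#' @param trace A (typically dF/F-normalized) [trace_matrix()].
#' @param events An [event_table()] data frame.
#' @param label Event label to align to.
#' @param window A [window_spec()].
#' @return A `peri_event_tensor`: list with `values` (neuron x trial x
#'   time array), `time_rel` (relative time axis, s), `neuron_ids`,
#'   `event_label`, `window`, `trials` (onsets used) and `excluded`
#'   (data frame of dropped trials with reasons).
#' @export
align_trials <- function(trace, events, label, window = window_spec()) {
  stopifnot(inherits(trace, "trace_matrix"))
  if (!label %in% events$event_label)
    stop("no events labelled '", label, "'; available: ",
         paste(unique(events$event_label), collapse = ", "))
  fs <- trace$sampling_rate_hz
  npre <- round(window$pre_s * fs)
  npost <- round(window$post_s * fs)
  ev <- events[events$event_label == label, , drop = FALSE]
  nt <- length(trace$times)
  keep <- integer(0)
  excluded <- data.frame(trial_index = integer(0), onset_s = numeric(0),
                         reason = character(0), stringsAsFactors = FALSE)
  idx0 <- integer(nrow(ev))
  for (j in seq_len(nrow(ev))) {
    i0 <- which(trace$times >= ev$onset_s[j] - 1e-9)[1L]
    idx0[j] <- if (length(i0)) i0 else NA_integer_
    if (is.na(idx0[j]) || idx0[j] - npre < 1L || idx0[j] + npost > nt) {
      excluded <- rbind(excluded, data.frame(
        trial_index = ev$trial_index[j], onset_s = ev$onset_s[j],
        reason = "window outside session", stringsAsFactors = FALSE))
    } else keep <- c(keep, j)
  }
  if (!length(keep)) stop("no event window fits within the session")
  vals <- array(NA_real_,
                dim = c(nrow(trace$values), length(keep), npre + npost + 1L),
                dimnames = list(trace$neuron_ids, NULL, NULL))
  for (k in seq_along(keep)) {
    cols <- (idx0[keep[k]] - npre):(idx0[keep[k]] + npost)
    vals[, k, ] <- trace$values[, cols]
  }
  structure(list(
    values = vals, time_rel = (-npre:npost) / fs,
    neuron_ids = trace$neuron_ids, event_label = label, window = window,
    trials = ev[keep, , drop = FALSE], excluded = excluded,
    zscored = FALSE), class = "peri_event_tensor")
}

#' @export
print.peri_event_tensor <- function(x, ...) {
  cat(sprintf(
    "<peri_event_tensor> %d neurons x %d trials x %d samples, %s [%g, +%g] s%s\n",
    dim(x$values)[1L], dim(x$values)[2L], dim(x$values)[3L], x$event_label,
    -x$window$pre_s, x$window$post_s,
    if (x$zscored) ", z-scored" else ""))
  if (nrow(x$excluded)) cat("  excluded trials:", nrow(x$excluded), "\n")
  invisible(x)
}

#' Peri-event Z-score normalization
#'
#' Aligns a trace to events and standardizes every neuron-trial slice by
#' its own pre-onset baseline F0 (the `[-pre_s, 0)` segment):
#' `z = (x - mean(F0)) / sd(F0)`, with the population SD (divisor N).
#' Trials whose baseline has zero SD are degenerate: their slices are set
#' to `NA` and counted in `degenerate`, with a warning.
#'
#' @inheritParams align_trials
#' @param per_trial Standardize by each trial's own baseline (default,
#'   matching the per-event formula) or by the per-neuron baseline pooled
#'   across trials.
#' @return A z-scored `peri_event_tensor` with an added `degenerate` data
#'   frame (neuron, trial pairs excluded).
#' @export
z_score <- function(trace, events, label, window = window_spec(),
                    per_trial = TRUE) {
  tensor <- align_trials(trace, events, label, window)
  base_idx <- which(tensor$time_rel < 0)
  dims <- dim(tensor$values)
  degen <- data.frame(neuron_id = character(0), trial = integer(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(dims[1L])) {
    if (per_trial) {
      for (j in seq_len(dims[2L])) {
        f0 <- tensor$values[i, j, base_idx]
        s <- pop_sd(f0)
        if (s == 0) {
          tensor$values[i, j, ] <- NA_real_
          degen <- rbind(degen, data.frame(
            neuron_id = tensor$neuron_ids[i], trial = j,
            stringsAsFactors = FALSE))
        } else {
          tensor$values[i, j, ] <- (tensor$values[i, j, ] - mean(f0)) / s
        }
      }
    } else {
      f0 <- as.vector(tensor$values[i, , base_idx])
      s <- pop_sd(f0)
      if (s == 0) {
        tensor$values[i, , ] <- NA_real_
        degen <- rbind(degen, data.frame(
          neuron_id = tensor$neuron_ids[i], trial = NA_integer_,
          stringsAsFactors = FALSE))
      } else {
        tensor$values[i, , ] <- (tensor$values[i, , ] - mean(f0)) / s
      }
    }
  }
  if (nrow(degen))
    warning(nrow(degen), " degenerate trial(s) with constant baseline ",
            "excluded from z-scoring")
  tensor$degenerate <- degen
  tensor$zscored <- TRUE
  tensor
}

# population (divisor N) standard deviation
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
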
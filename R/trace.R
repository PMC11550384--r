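#' Fluorescence trace matrix
#'
#' Container for one session of per-neuron fluorescence: a neurons x time
#' matrix with a uniform time axis. Values are raw F in arbitrary units, or
#' unitless dF/F after [delta_f_over_f()].
#'
#' @param values Numeric matrix, one row per neuron, one column per sample.
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param neuron_ids Character vector of neuron identifiers (default
#'   `"n1"..`).
#' @param sampling_rate_hz Sampling rate; inferred from `times` if missing.
#' @param phase Session/phase label (e.g. `"test"`).
#' @param normalized Logical; `TRUE` once values are dF/F.
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, times, neuron_ids = NULL,
                         sampling_rate_hz = NULL, phase = NA_character_,
                         normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("trace_matrix needs at least one neuron")
  if (length(times) != ncol(values))
    stop("length(times) must equal ncol(values)")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (length(dt) > 1L && max(abs(dt - dt[1L])) > 1e-6)
    stop("times must be uniformly spaced (within 1e-6 s)")
  if (anyNA(values)) stop("trace values must not contain NA")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(values)))
  if (anyDuplicated(neuron_ids)) stop("neuron_ids must be unique")
  if (is.null(sampling_rate_hz)) sampling_rate_hz <- 1 / dt[1L]
  rownames(values) <- neuron_ids
  structure(
    list(values = values, times = as.numeric(times),
         neuron_ids = as.character(neuron_ids),
         sampling_rate_hz = sampling_rate_hz,
         phase = phase, normalized = isTRUE(normalized)),
    class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf(
    "<trace_matrix> %d neurons x %d samples @ %.3g Hz, phase=%s, %s\n",
    nrow(x$values), ncol(x$values), x$sampling_rate_hz, x$phase,
    if (x$normalized) "dF/F" else "raw F"))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Event table constructor
#'
#' Timed cue/shock annotations for a session: one row per stimulus
#' presentation.
#'
#' @param event_label Character vector of labels (e.g. `"CS1"`, `"CS2"`,
#'   `"US"`).
#' @param onset_s,duration_s Numeric vectors, seconds.
#' @param phase Session phase label (recycled).
#' @param trial_index Integer trial number within event label; computed per
#'   label if missing.
#' @return A `data.frame` with columns `event_label`, `onset_s`,
#'   `duration_s`, `phase`, `trial_index`.
#' @export
event_table <- function(event_label, onset_s, duration_s,
                        phase = NA_character_, trial_index = NULL) {
  n <- length(onset_s)
  event_label <- rep_len(event_label, n)
  duration_s <- rep_len(duration_s, n)
  if (any(duration_s <= 0)) stop("event durations must be positive")
  if (is.null(trial_index)) {
    trial_index <- stats::ave(seq_len(n), event_label, FUN = seq_along)
  }
  df <- data.frame(event_label = as.character(event_label),
                   onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   phase = rep_len(as.character(phase), n),
                   trial_index = as.integer(trial_index),
                   stringsAsFactors = FALSE)
  df[order(df$onset_s), , drop = FALSE]
}

#' Read / write the session CSV dialects
#'
#' Traces are written with neurons as rows (`neuron_id` first column, one
#' column per timestamp); events and motion traces as plain column tables.
#'
#' @param trace A [trace_matrix()].
#' @param path File path.
#' @return `read_trace_csv()` returns a [trace_matrix()]; the writers
#'   return `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(neuron_id = trace$neuron_ids, trace$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("neuron_id", format_num(trace$times))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param phase,normalized Metadata not stored in the CSV; supply on read.
#' @export
read_trace_csv <- function(path, phase = NA_character_, normalized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  times <- as.numeric(colnames(df)[-1L])
  trace_matrix(as.matrix(df[, -1L, drop = FALSE]), times,
               neuron_ids = df[[1L]], phase = phase, normalized = normalized)
}

#' @rdname write_trace_csv
#' @param events An [event_table()] data frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_trace_csv
#' @param motion A motion-trace data frame (`time_s`, `motion`).
#' @export
write_motion_csv <- function(motion, path) {
  utils::write.csv(motion[, c("time_s", "motion")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_motion_csv <- function(path) {
  utils::read.csv(path)
}

# fixed-format numbers for reproducible CSV headers
format_num <- function(x) trimws(formatC(x, format = "fg", digits = 10))
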
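#' Configuration for a synthetic SOC experiment
#'
#' Bundles everything the generator needs to emit one full second-order
#' conditioning (SOC) study: the four-phase cue/shock schedule, planted
#' response-class fractions per phase, the calcium-kernel and noise model,
#' and the planted freezing schedule for the behavior simulator.
#'
#' The default schedule follows the standard SOC paradigm: a habituation
#' day with 10 light (CS1) and 10 tone (CS2) presentations in random order,
#' a first-order day with 10 CS1 trials co-terminating with a 0.5 s foot
#' shock (US), a second-order day with 4 CS2 -> 0.5 s gap -> CS1 pairings,
#' and a test day with 3 CS2 tones, all cues 10 s long with 2 min
#' inter-trial intervals (habituation 1-2 min, randomized).
#'
#' @param n_neurons Number of simulated neurons.
#' @param sampling_rate_hz Sampling rate of traces and motion (Hz).
#' @param phases Named list of phase descriptors; see
#'   [default_soc_phases()].
#' @param class_fractions Named list, one numeric vector per phase giving
#'   fractions of neurons per planted class
#'   (`us`, `cs1`, `cs2`, `sustained`, `inhibited`); the remainder is
#'   unresponsive. Fractions must sum to at most 1 per phase.
#' @param kernel List with `rise_tau_s`, `decay_tau_s`, `amplitude`
#'   (peak dF/F of a full-gain transient).
#' @param noise_sd Gaussian noise SD on the dF/F scale.
#' @param drift_amplitude Slow-baseline drift amplitude as a fraction of
#'   baseline fluorescence (sinusoid + linear trend).
#' @param drift_period_s Period of the sinusoidal drift component.
#' @param baseline_f Mean raw-fluorescence baseline (arbitrary units).
#' @param freeze_fractions Named list: `baseline` scalar plus one named
#'   vector per phase mapping event label to the planted fraction of cue
#'   time spent frozen (all in `[0, 1]`).
#' @param freeze_bout_s Mean freeze-bout duration of the two-state
#'   behavior model (s).
#' @param move_floor,move_sd Motion magnitude floor and jitter while the
#'   animal is moving.
#' @param dropout Per-session probability that a neuron is not imaged
#'   (longitudinal dropout).
#' @param fov_um Side of the square field holding footprint centroids
#'   (micrometres). The default scales with `n_neurons` to keep the
#'   density observed in the study (~26 neurons per 300 um field of
#'   view), since simulated cohorts pool neurons across animals.
#' @param centroid_jitter_um Per-session SD of observed centroid positions.
#' @param seed Integer seed; the same config is bit-reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 200,
                       sampling_rate_hz = 10,
                       phases = default_soc_phases(),
                       class_fractions = default_class_fractions(),
                       kernel = list(rise_tau_s = 0.2, decay_tau_s = 1.2,
                                     amplitude = 1),
                       noise_sd = 0.05,
                       drift_amplitude = 0.1,
                       drift_period_s = 300,
                       baseline_f = 100,
                       freeze_fractions = default_freeze_fractions(),
                       freeze_bout_s = 1.5,
                       move_floor = 1,
                       move_sd = 0.3,
                       dropout = 0.2,
                       fov_um = NULL,
                       centroid_jitter_um = 2,
                       seed = 1L) {
  stopifnot(n_neurons >= 1, sampling_rate_hz > 0, noise_sd >= 0,
            drift_amplitude >= 0, baseline_f > 0, dropout >= 0, dropout < 1,
            kernel$rise_tau_s > 0, kernel$decay_tau_s > kernel$rise_tau_s,
            freeze_bout_s > 0, move_floor >= 0)
  for (ph in names(phases)) {
    p <- phases[[ph]]
    durs <- unlist(p[grepl("_s$", names(p))])
    if (any(durs < 0) || p$cue_s <= 0)
      stop("non-positive duration in phase ", ph)
    if (abs(p$cue_s * sampling_rate_hz -
            round(p$cue_s * sampling_rate_hz)) > 1e-9)
      stop("cue duration in phase ", ph,
           " is not an integer number of samples")
  }
  for (ph in names(class_fractions)) {
    fr <- class_fractions[[ph]]
    if (length(fr) && (any(fr < 0) || sum(fr) > 1 + 1e-12))
      stop("class fractions for phase ", ph, " must be >= 0 and sum to <= 1")
    bad <- setdiff(names(fr), c("us", "cs1", "cs2", "sustained", "inhibited"))
    if (length(bad)) stop("unknown neuron class: ", paste(bad, collapse = ", "))
  }
  fz <- unlist(freeze_fractions)
  if (any(fz < 0 | fz > 1)) stop("freeze fractions must lie in [0, 1]")
  if (is.null(fov_um)) fov_um <- 300 * sqrt(n_neurons / 26)
  structure(list(
    n_neurons = as.integer(n_neurons), sampling_rate_hz = sampling_rate_hz,
    phases = phases, class_fractions = class_fractions, kernel = kernel,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    drift_period_s = drift_period_s, baseline_f = baseline_f,
    freeze_fractions = freeze_fractions, freeze_bout_s = freeze_bout_s,
    move_floor = move_floor, move_sd = move_sd, dropout = dropout,
    fov_um = fov_um, centroid_jitter_um = centroid_jitter_um,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default SOC phase descriptors
#'
#' @return Named list of the four phases (`habituation`, `cs1_us`,
#'   `cs2_cs1`, `test`) with trial counts, cue/US durations, the
#'   CS2 -> CS1 gap, inter-trial intervals and a pre-session baseline.
#' @export
default_soc_phases <- function() {
  list(
    habituation = list(n_cs1 = 10, n_cs2 = 10, cue_s = 10,
                       iti_range_s = c(60, 120), lead_in_s = 300,
                       tail_s = 30),
    cs1_us = list(n_trials = 10, cue_s = 10, us_s = 0.5, iti_s = 120,
                  lead_in_s = 300, tail_s = 30),
    cs2_cs1 = list(n_trials = 4, cue_s = 10, gap_s = 0.5, iti_s = 120,
                   lead_in_s = 300, tail_s = 30),
    test = list(n_trials = 3, cue_s = 10, iti_s = 120, lead_in_s = 300,
                tail_s = 30))
}

#' Default planted response-class fractions per phase
#'
#' Chosen to mirror the reported population proportions: modest innate cue
#' responses (and some cue-inhibited neurons) during habituation, a
#' US-dominated first-order day, a CS1-dominated pairing day, and a test
#' day where ~40% of neurons respond to the tone CS2 (a quarter of them
#' with activity sustained past cue offset) and a small fraction is
#' inhibited.
#'
#' @return Named list of per-phase fraction vectors.
#' @export
default_class_fractions <- function() {
  list(
    habituation = c(cs1 = 0.18, cs2 = 0.15, inhibited = 0.10),
    cs1_us = c(us = 0.60, cs1 = 0.25),
    cs2_cs1 = c(cs1 = 0.44, cs2 = 0.27),
    test = c(cs2 = 0.31, sustained = 0.10, inhibited = 0.06))
}

#' Default planted freezing schedule
#'
#' Fractions of cue time spent frozen: low innate freezing during
#' habituation, growing fear of the light CS1 across conditioning, and a
#' CS2 test response about two-thirds of the CS1 response so the planted
#' second-order memory-strength ratio is 66.7%.
#'
#' @return Named list: `baseline` scalar plus per-phase label vectors.
#' @export
default_freeze_fractions <- function() {
  list(baseline = 0.05,
       habituation = c(CS1 = 0.10, CS2 = 0.10),
       cs1_us = c(CS1 = 0.30),
       cs2_cs1 = c(CS1 = 0.60, CS2 = 0.30),
       test = c(CS2 = 0.40))
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

phase_offset <- function(phase) {
  match(phase, c("habituation", "cs1_us", "cs2_cs1", "test"),
        nomatch = 9L)
}

# deterministic block assignment of planted classes over global neuron index
class_of_index <- function(index, fractions, n_total) {
  classes <- names(fractions)
  counts <- floor(fractions * n_total + 0.5)
  while (sum(counts) > n_total) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  breaks <- cumsum(c(0, counts))
  out <- rep("unresponsive", length(index))
  for (k in seq_along(classes)) {
    out[index > breaks[k] & index <= breaks[k + 1L]] <- classes[k]
  }
  out
}

#' Event schedule for one SOC phase
#'
#' Generates the cue/US event table of a phase under the configured
#' paradigm. Habituation trial order and intervals are randomized
#' (reproducibly from the config seed); conditioning and test phases use
#' fixed 2-min intervals. Shock onsets co-terminate with CS1
#' (onset = CS1 onset + cue_s - us_s).
#'
#' @param config A [sim_config()].
#' @param phase One of `"habituation"`, `"cs1_us"`, `"cs2_cs1"`, `"test"`.
#' @return An [event_table()] data frame.
#' @export
phase_schedule <- function(config, phase) {
  if (!phase %in% names(config$phases))
    stop("unknown phase '", phase, "'; known: ",
         paste(names(config$phases), collapse = ", "))
  p <- config$phases[[phase]]
  fs <- config$sampling_rate_hz
  snap <- function(x) round(x * fs) / fs
  with_seed(config$seed + 7919L * phase_offset(phase), {
    if (phase == "habituation") {
      labels <- sample(c(rep("CS1", p$n_cs1), rep("CS2", p$n_cs2)))
      itis <- stats::runif(length(labels) - 1L, p$iti_range_s[1L],
                           p$iti_range_s[2L])
      onsets <- snap(p$lead_in_s + cumsum(c(0, itis + p$cue_s)))
      event_table(labels, onsets, rep(p$cue_s, length(labels)),
                  phase = phase)
    } else if (phase == "cs1_us") {
      o <- p$lead_in_s + (seq_len(p$n_trials) - 1L) * (p$cue_s + p$iti_s)
      event_table(c(rep("CS1", p$n_trials), rep("US", p$n_trials)),
                  snap(c(o, o + p$cue_s - p$us_s)),
                  c(rep(p$cue_s, p$n_trials), rep(p$us_s, p$n_trials)),
                  phase = phase)
    } else if (phase == "cs2_cs1") {
      pitch <- 2 * p$cue_s + p$gap_s + p$iti_s
      o <- p$lead_in_s + (seq_len(p$n_trials) - 1L) * pitch
      event_table(c(rep("CS2", p$n_trials), rep("CS1", p$n_trials)),
                  snap(c(o, o + p$cue_s + p$gap_s)),
                  rep(p$cue_s, 2L * p$n_trials), phase = phase)
    } else { # test
      o <- p$lead_in_s + (seq_len(p$n_trials) - 1L) * (p$cue_s + p$iti_s)
      event_table(rep("CS2", p$n_trials), snap(o),
                  rep(p$cue_s, p$n_trials), phase = phase)
    }
  })
}

# label of the cue that inhibited neurons respond to, per phase
primary_cue <- function(phase) {
  switch(phase, habituation = "CS2", cs1_us = "US", cs2_cs1 = "CS1",
         test = "CS2", "CS2")
}

# event label driven by each planted class
class_drive_label <- function(class, phase) {
  switch(class,
         us = "US", cs1 = "CS1", cs2 = "CS2", sustained = "CS2",
         inhibited = primary_cue(phase), NA_character_)
}

#' Simulate one SOC imaging session
#'
#' Emits raw fluorescence traces (baseline x (1 + drift + event-locked
#' transients + noise)), the phase's event table and a ground-truth record
#' per neuron. Transients are the event boxcar (extended 10 s past cue
#' offset for the `sustained` class) convolved with the double-exponential
#' calcium kernel, peak-normalized so a neuron's planted gain is its peak
#' dF/F response; `inhibited` neurons receive the negated drive at half
#' gain. Identical `config` and `phase` give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param phase Phase name.
#' @param neurons Optional persistent per-neuron parameter table from
#'   [simulate_experiment()] (columns `neuron_id`, `index`, `gain_mult`,
#'   `latency_s`, `baseline_f`); drawn fresh when `NULL`.
#' @return List with elements `trace` ([trace_matrix()]), `events`
#'   ([event_table()]) and `truth` (data frame: `neuron_id`, `class`,
#'   `gain`, `latency_s`, `baseline_f`).
#' @export
simulate_session <- function(config, phase, neurons = NULL) {
  events <- phase_schedule(config, phase)
  fs <- config$sampling_rate_hz
  dt <- 1 / fs
  p <- config$phases[[phase]]
  t_end <- max(events$onset_s + events$duration_s) + p$tail_s
  times <- seq(0, t_end, by = dt)
  nt <- length(times)

  with_seed(config$seed + 7919L * phase_offset(phase) + 17L, {
    if (is.null(neurons)) {
      neurons <- draw_neuron_params(config)
    }
    n <- nrow(neurons)
    fractions <- config$class_fractions[[phase]]
    if (is.null(fractions)) fractions <- numeric(0)
    cls <- class_of_index(neurons$index, fractions, config$n_neurons)

    # peak-normalized response shape per (label, sustained?) combination
    kern_t <- seq(0, 8 * config$kernel$decay_tau_s, by = dt)
    kern <- calcium_kernel(kern_t, config$kernel$rise_tau_s,
                           config$kernel$decay_tau_s, 1)
    shape_for <- function(label, sustain) {
      drive <- numeric(nt)
      ev <- events[events$event_label == label, , drop = FALSE]
      for (j in seq_len(nrow(ev))) {
        i0 <- round(ev$onset_s[j] * fs) + 1L
        dur <- ev$duration_s[j] + if (sustain) 10 else 0
        i1 <- min(nt, i0 + round(dur * fs) - 1L)
        if (i0 <= nt) drive[i0:i1] <- 1
      }
      resp <- stats::convolve(drive, rev(kern), type = "open")[seq_len(nt)]
      mx <- max(resp)
      if (mx > 0) resp / mx else resp
    }
    labs <- vapply(cls, class_drive_label, "", phase = phase)
    shapes <- list()
    for (combo in unique(paste(labs[!is.na(labs)],
                               (cls == "sustained")[!is.na(labs)]))) {
      parts <- strsplit(combo, " ")[[1L]]
      shapes[[combo]] <- shape_for(parts[1L], as.logical(parts[2L]))
    }

    drift_phi <- stats::runif(n, 0, 2 * pi)
    values <- matrix(0, n, nt)
    lin <- 2 * (times - t_end / 2) / t_end
    for (i in seq_len(n)) {
      sig <- numeric(nt)
      lab <- class_drive_label(cls[i], phase)
      if (!is.na(lab)) {
        combo <- paste(lab, cls[i] == "sustained")
        base <- shapes[[combo]]
        shift <- round(neurons$latency_s[i] * fs)
        if (shift > 0)
          base <- c(numeric(shift), base[seq_len(nt - shift)])
        gain <- config$kernel$amplitude * neurons$gain_mult[i]
        if (cls[i] == "inhibited") gain <- -0.5 * gain
        sig <- gain * base
      }
      drift <- config$drift_amplitude *
        (0.7 * sin(2 * pi * times / config$drift_period_s + drift_phi[i]) +
           0.3 * lin)
      noise <- if (config$noise_sd > 0)
        stats::rnorm(nt, 0, config$noise_sd) else 0
      values[i, ] <- neurons$baseline_f[i] * (1 + drift + sig + noise)
    }
    truth <- data.frame(neuron_id = neurons$neuron_id, class = cls,
                        gain = config$kernel$amplitude * neurons$gain_mult,
                        latency_s = neurons$latency_s,
                        baseline_f = neurons$baseline_f,
                        stringsAsFactors = FALSE)
    list(trace = trace_matrix(values, times, neurons$neuron_id,
                              sampling_rate_hz = fs, phase = phase),
         events = events, truth = truth)
  })
}

draw_neuron_params <- function(config, index = seq_len(config$n_neurons)) {
  n <- length(index)
  data.frame(
    neuron_id = sprintf("n%03d", index), index = index,
    gain_mult = stats::runif(n, 0.7, 1.3),
    latency_s = stats::runif(n, 0, 0.2),
    baseline_f = config$baseline_f * stats::runif(n, 0.8, 1.2),
    stringsAsFactors = FALSE)
}

#' Simulate freezing behavior for a session
#'
#' Two-state (freeze/move) Markov chain at the imaging sampling rate whose
#' stationary freeze probability is the planted freeze fraction: the
#' configured `baseline` fraction outside cues and the per-label planted
#' fraction inside each cue window. The state is redrawn from the new
#' stationary distribution whenever the planted probability changes
#' (cue-evoked freezing onsets are effectively immediate), so window-level
#' freeze fractions are unbiased. Motion is 0 while frozen and
#' `move_floor` plus half-normal jitter while moving. With
#' `stochastic = FALSE` the animal instead freezes for exactly the first
#' planted fraction of every cue window (and never at baseline), which
#' recovers plants exactly.
#'
#' @param config A [sim_config()].
#' @param events An [event_table()] for one phase.
#' @param stochastic Use the Markov bout model (default) or the
#'   deterministic schedule.
#' @return Data frame `time_s`, `motion` with attributes `freeze_state`
#'   (logical vector) and `planted` (named planted fractions used).
#' @export
simulate_behavior <- function(config, events, stochastic = TRUE) {
  if (nrow(events) == 0L) stop("events must be non-empty")
  phase <- events$phase[1L]
  fs <- config$sampling_rate_hz
  dt <- 1 / fs
  t_end <- max(events$onset_s + events$duration_s) +
    config$phases[[phase]]$tail_s
  times <- seq(0, t_end, by = dt)
  nt <- length(times)

  planted <- config$freeze_fractions[[phase]]
  p <- rep(config$freeze_fractions$baseline, nt)
  cue_mask <- logical(nt)
  for (lab in unique(events$event_label)) {
    ev <- events[events$event_label == lab, , drop = FALSE]
    if (nrow(ev) > 1L) {
      off <- ev$onset_s + ev$duration_s
      if (any(ev$onset_s[-1L] < off[-nrow(ev)] - 1e-9))
        stop("overlapping cue windows for label ", lab)
    }
    if (!lab %in% names(planted)) next
    for (j in seq_len(nrow(ev))) {
      idx <- which(times >= ev$onset_s[j] - 1e-9 &
                     times < ev$onset_s[j] + ev$duration_s[j] - 1e-9)
      p[idx] <- planted[[lab]]
      cue_mask[idx] <- TRUE
    }
  }

  with_seed(config$seed + 104729L + phase_offset(phase), {
    frozen <- logical(nt)
    if (stochastic) {
      p_exit <- dt / config$freeze_bout_s
      frozen[1L] <- stats::runif(1) < p[1L]
      u <- stats::runif(nt)
      for (i in 2L:nt) {
        if (p[i] != p[i - 1L]) { # planted level changed: redraw state
          frozen[i] <- u[i] < p[i]
        } else if (frozen[i - 1L]) {
          frozen[i] <- if (p[i] >= 1) TRUE else u[i] >= p_exit
        } else {
          pe <- if (p[i] >= 1) 1 else min(1, p[i] * p_exit / (1 - p[i]))
          frozen[i] <- u[i] < pe
        }
      }
    } else {
      for (j in seq_len(nrow(events))) {
        lab <- events$event_label[j]
        if (!lab %in% names(planted)) next
        i0 <- which(times >= events$onset_s[j] - 1e-9)[1L]
        nwin <- round(events$duration_s[j] * fs)
        nfr <- round(planted[[lab]] * nwin)
        if (nfr > 0) frozen[i0:(i0 + nfr - 1L)] <- TRUE
      }
    }
    motion <- ifelse(frozen, 0,
                     config$move_floor +
                       abs(stats::rnorm(nt, 0, config$move_sd)))
    out <- data.frame(time_s = times, motion = motion)
    attr(out, "freeze_state") <- frozen
    attr(out, "planted") <- planted
    out
  })
}

#' Simulate a full multi-session SOC experiment
#'
#' Draws persistent per-neuron parameters and footprint centroids once,
#' applies per-session dropout, and simulates every configured phase
#' (traces, events, behavior) plus per-session observed centroids with
#' registration jitter. The returned correspondence table is the oracle
#' for longitudinal-matching tests.
#'
#' @param config A [sim_config()].
#' @param phases Phases to simulate (default: all configured).
#' @return List with `sessions` (per phase: `trace`, `events`, `truth`,
#'   `motion`, `centroids`), `neurons` (persistent parameters incl. true
#'   centroids) and `presence` (logical neurons x phases matrix).
#' @export
simulate_experiment <- function(config, phases = names(config$phases)) {
  master <- with_seed(config$seed + 541L, {
    neurons <- draw_neuron_params(config)
    neurons$x_um <- stats::runif(config$n_neurons, 0, config$fov_um)
    neurons$y_um <- stats::runif(config$n_neurons, 0, config$fov_um)
    presence <- matrix(stats::runif(config$n_neurons * length(phases)) >=
                         config$dropout,
                       config$n_neurons, length(phases),
                       dimnames = list(neurons$neuron_id, phases))
    list(neurons = neurons, presence = presence)
  })
  sessions <- list()
  for (s in seq_along(phases)) {
    ph <- phases[s]
    keep <- master$presence[, s]
    ses <- simulate_session(config, ph, neurons = master$neurons[keep, ])
    ses$motion <- simulate_behavior(config, ses$events)
    ses$centroids <- with_seed(config$seed + 104729L * 2L + s, {
      data.frame(
        neuron_id = master$neurons$neuron_id[keep],
        x_um = master$neurons$x_um[keep] +
          stats::rnorm(sum(keep), 0, config$centroid_jitter_um),
        y_um = master$neurons$y_um[keep] +
          stats::rnorm(sum(keep), 0, config$centroid_jitter_um),
        stringsAsFactors = FALSE)
    })
    sessions[[ph]] <- ses
  }
  list(sessions = sessions, neurons = master$neurons,
       presence = master$presence, config = config)
}
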
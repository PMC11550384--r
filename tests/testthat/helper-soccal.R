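# shared fixtures: scaled-down paradigm and planted response archetypes

small_phases <- function() {
  list(
    habituation = list(n_cs1 = 4, n_cs2 = 4, cue_s = 10,
                       iti_range_s = c(30, 60), lead_in_s = 60, tail_s = 30),
    cs1_us = list(n_trials = 4, cue_s = 10, us_s = 0.5, iti_s = 60,
                  lead_in_s = 60, tail_s = 30),
    cs2_cs1 = list(n_trials = 4, cue_s = 10, gap_s = 0.5, iti_s = 60,
                   lead_in_s = 60, tail_s = 30),
    test = list(n_trials = 3, cue_s = 10, iti_s = 60, lead_in_s = 60,
                tail_s = 30))
}

small_config <- function(n = 40, seed = 1, ...) {
  sim_config(n_neurons = n, phases = small_phases(), seed = seed, ...)
}

# k well-separated response archetypes (distinct transient timings within
# the -10..+20 s window, last one unresponsive) plus isotropic noise
archetype_traces <- function(n_per = 40, archetypes = 1:5, noise_sd = 0.3,
                             amplitude = 3, seed = 1) {
  tt <- seq(-10, 20, by = 0.1)
  shapes <- rbind(
    calcium_kernel(tt, 0.3, 1.2) * (tt >= 0),
    calcium_kernel(tt - 4, 0.3, 1.2) * (tt >= 4),
    calcium_kernel(tt - 8, 0.3, 1.2) * (tt >= 8),
    calcium_kernel(tt - 13, 0.3, 1.2) * (tt >= 13),
    rep(0, length(tt)))
  k <- length(archetypes)
  truth <- rep(seq_len(k), each = n_per)
  x <- shapes[archetypes[truth], , drop = FALSE] * amplitude
  withr::with_seed(seed, {
    x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x))
  })
  rownames(x) <- sprintf("n%03d", seq_len(nrow(x)))
  attr(x, "time_rel") <- tt
  attr(x, "truth") <- truth
  x
}

# dF/F-normalized trace + events for one simulated phase
sim_normalized <- function(config, phase) {
  ses <- simulate_session(config, phase)
  list(dff = delta_f_over_f(ses$trace), events = ses$events,
       truth = ses$truth)
}

expected_category <- function(class) {
  c(us = "no_change", cs1 = "no_change", cs2 = "increased",
    sustained = "increased", inhibited = "decreased",
    unresponsive = "no_change")[class]
}
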
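# Shared study configuration for the analysis scripts.
#
# The synthetic study mirrors the standard SOC paradigm: habituation
# (10 CS1 + 10 CS2), CS1-US (10 trials, co-terminating 0.5 s shock),
# CS2-CS1 (4 pairings, 0.5 s gap), test (3 CS2), 10 Hz sampling,
# 200 neurons with the default planted response-class fractions.
# Sourced by the numbered scripts; the simulated experiment is cached
# under scratch/ so later stages do not re-simulate.

library(soccal)

STUDY_SEED <- 1L
RESULTS <- "results"
SCRATCH <- "scratch"

study_config <- function(seed = STUDY_SEED) sim_config(seed = seed)

get_experiment <- function() {
  dir.create(SCRATCH, showWarnings = FALSE)
  cache <- file.path(SCRATCH, sprintf("experiment_seed%d.rds", STUDY_SEED))
  if (file.exists(cache)) return(readRDS(cache))
  exp <- simulate_experiment(study_config())
  saveRDS(exp, cache)
  exp
}

out_path <- function(...) {
  dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
  file.path(RESULTS, ...)
}

primary_cue_of <- c(habituation = "CS2", cs1_us = "CS1",
                    cs2_cs1 = "CS2", test = "CS2")
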
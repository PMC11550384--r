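#!/usr/bin/env Rscript
# Normalize each session (whole-trace dF/F), align to the phase's primary
# cue, z-score against the -10..0 s baseline and tabulate pre/post AUC
# per neuron. Writes one AUC table per phase plus the population-average
# peri-event traces used for the figures.

source("analysis/00_config.R")

exp <- get_experiment()

for (ph in names(exp$sessions)) {
  ses <- exp$sessions[[ph]]
  cue <- primary_cue_of[[ph]]
  dff <- delta_f_over_f(ses$trace)
  tensor <- align_trials(dff, ses$events, cue, window_spec(10, 20))
  ztensor <- z_score(dff, ses$events, cue, window_spec(10, 20))
  auc <- peri_auc(tensor)
  utils::write.csv(auc, out_path(sprintf("auc_%s.csv", ph)),
                   row.names = FALSE)
  pop <- population_average(trial_average(ztensor))
  utils::write.csv(pop, out_path(sprintf("population_trace_%s.csv", ph)),
                   row.names = FALSE)
  peak <- pop$time_rel[which.max(pop$mean)]
  cat(sprintf(
    "%-12s cue %s: %d/%d trials aligned, %d degenerate; population z peaks at %+.1f s (%.2f)\n",
    ph, cue, nrow(tensor$trials),
    nrow(tensor$trials) + nrow(tensor$excluded),
    nrow(ztensor$degenerate), peak, max(pop$mean)))
}
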
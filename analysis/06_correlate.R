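#!/usr/bin/env Rscript
# Within-state maximum pairwise correlations on the test day: every
# neuron's best Pearson correlation with any partner during the
# pre-session baseline vs during the tone CS2 windows, compared by
# Cohen's d.

source("analysis/00_config.R")

exp <- get_experiment()
ses <- exp$sessions$test
dff <- delta_f_over_f(ses$trace)

comp <- compare_state_correlations(
  dff,
  state_windows(ses$events, "baseline"),
  state_windows(ses$events, "CS2"),
  states = c("baseline", "tone"))

utils::write.csv(comp$per_neuron, out_path("state_correlations.csv"),
                 row.names = FALSE)
means <- tapply(comp$per_neuron$max_r, comp$per_neuron$state, mean)
cat(sprintf("mean max pairwise r: baseline %.3f, tone %.3f (n = %d, %d)\n",
            means[["baseline"]], means[["tone"]], comp$n[1], comp$n[2]))
cat(sprintf("Cohen's d (baseline - tone): %.3f\n", comp$d))
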
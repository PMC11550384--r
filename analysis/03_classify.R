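#!/usr/bin/env Rscript
# Classify neurons by the >50% AUC-ratio rule per phase, report the
# population proportions, recover the planted fractions, and partition
# CS2 responders of the pairing phase by their CS1 responsiveness
# (CS1/CS2-encoding vs CS2-only).

source("analysis/00_config.R")

exp <- get_experiment()

for (ph in names(exp$sessions)) {
  auc <- utils::read.csv(out_path(sprintf("auc_%s.csv", ph)))
  cl <- classify_responses(auc, pre_window_s = 10)
  utils::write.csv(cl, out_path(sprintf("classification_%s.csv", ph)),
                   row.names = FALSE)
  s <- summarize_population(cl)
  utils::write.csv(s, out_path(sprintf("summary_%s.csv", ph)),
                   row.names = FALSE)
  # agreement diagnostic against the plant, restricted to neurons whose
  # expected category under this alignment is unambiguous: classes driven
  # by the aligned cue (-> increased), inhibited (-> decreased) and
  # unresponsive (-> no_change); classes driven by a different event are
  # skipped since their windows overlap the aligned one only partially
  cue <- primary_cue_of[[ph]]
  driven <- c(us = "US", cs1 = "CS1", cs2 = "CS2", sustained = "CS2")
  truth <- exp$sessions[[ph]]$truth
  cls_n <- truth$class[match(cl$neuron_id, truth$neuron_id)]
  expected <- ifelse(cls_n == "inhibited", "decreased",
                     ifelse(cls_n == "unresponsive", "no_change",
                            ifelse(driven[cls_n] == cue, "increased", NA)))
  agree <- mean(expected == as.character(cl$category), na.rm = TRUE)
  cat(sprintf("%-12s %s | planted agreement %.1f%% (%d scoreable)\n", ph,
              paste(s$category, sprintf("%d (%.1f%%)", s$count, s$percent),
                    collapse = ", "),
              100 * agree, sum(!is.na(expected))))
}

# shock-locked view of the conditioning day: align to US onset instead of
# the light, so innately shock-driven neurons land in the post window
ses_us <- exp$sessions$cs1_us
cl_us <- classify_responses(peri_auc(align_trials(
  delta_f_over_f(ses_us$trace), ses_us$events, "US", window_spec(10, 20))))
utils::write.csv(cl_us, out_path("classification_cs1_us_shock_locked.csv"),
                 row.names = FALSE)
s_us <- summarize_population(cl_us)
n_us_class <- sum(ses_us$truth$class == "us")
cat(sprintf(
  "cs1_us (shock-locked): %d/%d increased; %d neurons are planted US-responders\n",
  s_us$count[s_us$category == "increased"], attr(s_us, "n_total"),
  n_us_class))

# cue-overlap on the pairing day: who encodes CS1, CS2 or both?
ses <- exp$sessions$cs2_cs1
dff <- delta_f_over_f(ses$trace)
cls <- lapply(c("CS1", "CS2"), function(lab)
  classify_responses(peri_auc(align_trials(dff, ses$events, lab,
                                           window_spec(10, 20)))))
ov <- encode_overlap(cls[[1]], cls[[2]])
utils::write.csv(ov, out_path("overlap_cs2_cs1.csv"), row.names = FALSE)
cat("\nCS1/CS2 overlap (pairing phase):\n")
print(ov, row.names = FALSE)
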
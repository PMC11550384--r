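test_that("phase schedules follow the SOC paradigm", {
  cfg <- sim_config(n_neurons = 4)
  ev <- phase_schedule(cfg, "cs1_us")
  cs1 <- ev[ev$event_label == "CS1", ]
  us <- ev[ev$event_label == "US", ]
  expect_equal(nrow(cs1), 10)
  expect_equal(nrow(us), 10)
  # shock co-terminates with the light: onset + 9.5 s, 0.5 s long
  expect_equal(us$onset_s, cs1$onset_s + 9.5)
  expect_equal(us$duration_s, rep(0.5, 10))
  expect_equal(us$onset_s + us$duration_s, cs1$onset_s + cs1$duration_s)

  ev2 <- phase_schedule(cfg, "cs2_cs1")
  cs2 <- ev2[ev2$event_label == "CS2", ]
  cs1b <- ev2[ev2$event_label == "CS1", ]
  expect_equal(nrow(cs2), 4)
  # light follows tone offset by 0.5 s
  expect_equal(cs1b$onset_s, cs2$onset_s + cs2$duration_s + 0.5)

  expect_equal(sum(phase_schedule(cfg, "test")$event_label == "CS2"), 3)
  hab <- phase_schedule(cfg, "habituation")
  expect_equal(as.integer(table(hab$event_label)[c("CS1", "CS2")]),
               c(10L, 10L))
  expect_error(phase_schedule(cfg, "recall"), "unknown phase")
})

test_that("event-row count equals the summed trial counts", {
  cfg <- small_config()
  counts <- c(habituation = 8, cs1_us = 8, cs2_cs1 = 8, test = 3)
  for (ph in names(counts)) {
    expect_equal(nrow(phase_schedule(cfg, ph)), unname(counts[ph]))
  }
})

test_that("simulation is bit-reproducible and seed-sensitive", {
  cfg <- small_config(n = 6)
  a <- simulate_session(cfg, "test")
  b <- simulate_session(cfg, "test")
  expect_identical(a, b)
  d <- simulate_session(small_config(n = 6, seed = 2), "test")
  expect_false(identical(a$trace$values, d$trace$values))
  ma <- simulate_behavior(cfg, a$events)
  mb <- simulate_behavior(cfg, b$events)
  expect_identical(ma, mb)
})

test_that("noiseless all-unresponsive traces are exactly baseline + drift", {
  cfg <- small_config(n = 20, noise_sd = 0,
                      class_fractions = list(test = numeric(0)))
  ses <- simulate_session(cfg, "test")
  expect_true(all(ses$truth$class == "unresponsive"))
  # remove the per-neuron baseline scaling: residual is pure drift, so a
  # sinusoid + linear trend bounded by the drift amplitude
  rel <- sweep(ses$trace$values, 1, ses$truth$baseline_f, "/") - 1
  expect_lte(max(abs(rel)), cfg$drift_amplitude + 1e-12)
  # and classification downstream finds nothing responsive
  cl <- classify_responses(peri_auc(align_trials(
    delta_f_over_f(ses$trace), ses$events, "CS2", window_spec(10, 20))))
  expect_true(all(cl$category == "no_change"))
})

test_that("kernel peak matches its analytic peak time within one sample", {
  dt <- 0.1
  tt <- seq(0, 10, by = dt)
  k <- calcium_kernel(tt, 0.2, 1.2)
  expect_lte(abs(tt[which.max(k)] - kernel_peak_time(0.2, 1.2)), dt)
  expect_equal(calcium_kernel(kernel_peak_time(0.2, 1.2), 0.2, 1.2), 1)
  # also at a different tau pair and finer sampling
  tt2 <- seq(0, 20, by = 0.01)
  k2 <- calcium_kernel(tt2, 0.5, 3, amplitude = 2)
  expect_lte(abs(tt2[which.max(k2)] - kernel_peak_time(0.5, 3)), 0.01)
  expect_equal(calcium_kernel(kernel_peak_time(0.5, 3), 0.5, 3,
                              amplitude = 2), 2)
})

test_that("noiseless simulated transients peak where the kernel predicts", {
  # US drive is nearly an impulse (0.5 s), so the response peak should sit
  # close to onset + kernel peak time
  cfg <- small_config(n = 4, noise_sd = 0, drift_amplitude = 0,
                      class_fractions = list(cs1_us = c(us = 1)))
  ses <- simulate_session(cfg, "cs1_us")
  us1 <- ses$events[ses$events$event_label == "US", ][1L, ]
  idx <- which(ses$trace$times >= us1$onset_s &
                 ses$trace$times <= us1$onset_s + 6)
  i <- idx[which.max(ses$trace$values[1L, idx])]
  lag <- ses$trace$times[i] - us1$onset_s - ses$truth$latency_s[1L]
  expect_lte(abs(lag - kernel_peak_time(0.2, 1.2)),
             0.5 + 2 / cfg$sampling_rate_hz) # boxcar widens peak by <= 0.5 s
})

test_that("config validation rejects impossible setups", {
  expect_error(sim_config(class_fractions = list(test = c(cs2 = 0.8,
                                                          inhibited = 0.4))),
               "sum to <= 1")
  expect_error(sim_config(class_fractions = list(test = c(tone = 0.5))),
               "unknown neuron class")
  expect_error(sim_config(freeze_fractions = list(baseline = 1.2)),
               "freeze fractions")
  ph <- default_soc_phases()
  ph$test$cue_s <- -1
  expect_error(sim_config(phases = ph), "duration")
})

test_that("planted full freezing silences motion in every cue window", {
  cfg <- small_config(freeze_fractions = list(baseline = 0.05,
                                              test = c(CS2 = 1)))
  ev <- phase_schedule(cfg, "test")
  m <- simulate_behavior(cfg, ev)
  for (j in seq_len(nrow(ev))) {
    idx <- which(m$time_s >= ev$onset_s[j] &
                   m$time_s < ev$onset_s[j] + ev$duration_s[j] - 1e-9)
    expect_true(all(m$motion[idx] == 0))
  }
})

test_that("zero planted baseline freezing keeps motion above the floor", {
  cfg <- small_config(freeze_fractions = list(baseline = 0,
                                              test = c(CS2 = 0.5)))
  ev <- phase_schedule(cfg, "test")
  m <- simulate_behavior(cfg, ev)
  base_idx <- which(m$time_s < min(ev$onset_s))
  expect_true(all(m$motion[base_idx] >= cfg$move_floor))
  fr <- freezing_percent(m, event_table("probe", 5, 30, phase = "test"),
                         labels = "probe", min_bout_s = 0)
  expect_equal(fr$freeze_percent, 0)
})

test_that("overlapping same-label cue windows are rejected", {
  cfg <- small_config()
  ev <- event_table(c("CS2", "CS2"), c(100, 105), c(10, 10), phase = "test")
  expect_error(simulate_behavior(cfg, ev), "overlapping")
  expect_error(simulate_behavior(cfg, ev[0, ]), "non-empty")
})

test_that("experiment-level dropout and correspondence are consistent", {
  cfg <- small_config(n = 30, dropout = 0.2)
  ex <- simulate_experiment(cfg, phases = c("habituation", "test"))
  for (ph in names(ex$sessions)) {
    ids <- ex$sessions[[ph]]$trace$neuron_ids
    expect_setequal(ids, rownames(ex$presence)[ex$presence[, ph]])
    expect_identical(ids, ex$sessions[[ph]]$centroids$neuron_id)
    # one ground-truth record per emitted trace row
    expect_identical(ids, ex$sessions[[ph]]$truth$neuron_id)
  }
})
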
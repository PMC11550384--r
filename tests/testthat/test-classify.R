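mk_auc <- function(pre, post) {
  structure(data.frame(neuron_id = sprintf("n%02d", seq_along(pre)),
                       auc_pre = pre, auc_post = post,
                       stringsAsFactors = FALSE),
            pre_window_s = 10)
}

test_that("the >50% AUC-ratio rule is applied with strict boundaries", {
  cl <- classify_responses(mk_auc(c(1, 1, 1, 1, 1),
                                  c(1.6, 1.5, 0.4, 0.5, 1.0)))
  expect_equal(as.character(cl$category),
               c("increased", "no_change", "decreased", "no_change",
                 "no_change"))
  expect_equal(cl$effective_ratio, c(1.6, 1.5, 0.4, 0.5, 1.0))
})

test_that("near-zero or negative baselines fall back to the difference rule", {
  # lone record, zero baseline spread: eps floor = 0.1 (1% of 10 s window)
  cl <- classify_responses(mk_auc(0, 3))
  expect_equal(as.character(cl$category), "increased")
  cl2 <- classify_responses(mk_auc(-2, -4.5))
  expect_equal(as.character(cl2$category), "decreased")
  cl3 <- classify_responses(mk_auc(0.05, 0.06))
  expect_equal(as.character(cl3$category), "no_change")
  expect_true(is.na(cl3$effective_ratio))
  # non-finite AUC is degenerate, and categories always partition
  cl4 <- classify_responses(mk_auc(c(NA, 1), c(1, 2)))
  expect_equal(as.character(cl4$category), c("degenerate", "increased"))
})

test_that("classification is invariant to positive rescaling of both AUCs", {
  set.seed(13)
  pre <- c(stats::rnorm(30, 0, 0.2), stats::runif(10, 2, 6))
  post <- c(stats::rnorm(30, 0, 0.2), stats::runif(10, 1, 12))
  base <- classify_responses(mk_auc(pre, post))
  for (a in c(0.01, 5, 1000)) {
    scaled <- classify_responses(mk_auc(a * pre, a * post))
    expect_equal(as.character(scaled$category),
                 as.character(base$category))
  }
})

test_that("population summaries reproduce printed count/percent pairs", {
  expect_equal(percent1(53, 122), 43.4)
  expect_equal(percent1(25, 53), 47.2)
  expect_equal(percent1(76, 122), 62.3)
  expect_equal(percent1(0, 57), 0)
  # half-up at the boundary (base round() would give 43.4 here)
  expect_equal(percent1(4345, 10000), 43.5)
  cl <- classify_responses(mk_auc(c(rep(1, 122)),
                                  c(rep(2, 53), rep(1, 62), rep(0.2, 7))))
  s <- summarize_population(cl)
  expect_equal(s$count[s$category == "increased"], 53L)
  expect_equal(s$percent[s$category == "increased"], 43.4)
  expect_equal(sum(s$count), 122L)
  expect_equal(attr(s, "n_total"), 122L)
})

test_that("duplicate neuron ids are rejected in summaries", {
  cl <- classify_responses(mk_auc(c(1, 1), c(2, 2)))
  cl$neuron_id <- c("a", "a")
  expect_error(summarize_population(cl), "duplicate")
})

test_that("cue-overlap partitions responders consistently", {
  a <- classify_responses(mk_auc(rep(1, 10),
                                 c(rep(2, 4), rep(1, 6))))  # 4 respond
  b <- classify_responses(mk_auc(rep(1, 10),
                                 c(rep(1, 4), rep(2, 3), rep(1, 3))))
  ov <- encode_overlap(a, b)
  expect_equal(ov$count, c(0L, 4L, 3L, 3L))  # disjoint responders
  expect_equal(sum(ov$count), 10L)
  ov2 <- encode_overlap(a, a)
  expect_equal(ov2$count[ov2$group %in% c("CS1_only", "CS2_only")],
               c(0L, 0L))
  expect_equal(attr(ov2, "percent_of_b_responders"), 100)
  b$neuron_id[1] <- "zz"
  expect_error(encode_overlap(a, b), "universes")
})

test_that("planted cue-encoding overlap is recovered exactly without noise", {
  cfg <- small_config(n = 40, noise_sd = 0,
                      class_fractions = list(cs2_cs1 = c(cs1 = 0.4,
                                                         cs2 = 0.2)))
  s <- sim_normalized(cfg, "cs2_cs1")
  cls <- lapply(c("CS1", "CS2"), function(lab)
    classify_responses(peri_auc(align_trials(s$dff, s$events, lab,
                                             window_spec(10, 20)))))
  ov <- encode_overlap(cls[[1]], cls[[2]])
  # planted classes are exclusive: 16 CS1-only, 8 CS2-only, no overlap
  expect_equal(ov$count, c(0L, 16L, 8L, 16L))
})

test_that("noiseless planted classes are recovered with full agreement", {
  cfg <- small_config(n = 50, noise_sd = 0,
                      class_fractions = list(test = c(cs2 = 0.3,
                                                      sustained = 0.1,
                                                      inhibited = 0.1)))
  s <- sim_normalized(cfg, "test")
  cl <- classify_responses(peri_auc(align_trials(s$dff, s$events, "CS2",
                                                 window_spec(10, 20))))
  expect_equal(as.character(cl$category),
               unname(expected_category(s$truth$class)))
})
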
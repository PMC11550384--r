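feat <- function(ids, centroids = NULL, traces = NULL) {
  out <- list(neuron_ids = ids)
  if (!is.null(centroids)) out$centroids <- centroids
  if (!is.null(traces)) out$ref_traces <- traces
  out
}

test_that("identical feature sets match one-to-one with score 1", {
  set.seed(31)
  cent <- cbind(stats::runif(8, 0, 300), stats::runif(8, 0, 300))
  tr <- matrix(stats::rnorm(8 * 50), 8)
  a <- feat(paste0("n", 1:8), cent, tr)
  m <- match_sessions(a, a)
  expect_equal(nrow(m), 8L)
  expect_equal(m$id_a, m$id_b)
  expect_equal(m$score, rep(1, 8))
  expect_length(attr(m, "unmatched_a"), 0L)
})

test_that("uniformly sub-threshold correlations yield no matches", {
  # all pairwise trace correlations ~0.4 < 0.5 minimum: nothing accepted
  set.seed(32)
  shared <- stats::rnorm(400)
  mk <- function(n) t(vapply(seq_len(n),
                             function(i) sqrt(0.4) * shared +
                               sqrt(0.6) * stats::rnorm(400),
                             numeric(400)))
  a <- feat(paste0("a", 1:5), traces = mk(5))
  b <- feat(paste0("b", 1:5), traces = mk(5))
  m <- match_sessions(a, b)
  r <- stats::cor(t(a$ref_traces), t(b$ref_traces))
  expect_true(all(r < 0.5))
  expect_equal(nrow(m), 0L)
  expect_length(attr(m, "unmatched_a"), 5L)
})

test_that("matching is one-to-one, symmetric and deterministic", {
  cfg <- small_config(n = 60, seed = 33)
  ex <- simulate_experiment(cfg, phases = c("habituation", "test"))
  f <- lapply(ex$sessions, function(s)
    feat(s$centroids$neuron_id,
         as.matrix(s$centroids[, c("x_um", "y_um")])))
  m1 <- match_sessions(f[[1]], f[[2]], weights = c(spatial = 1, trace = 0))
  m2 <- match_sessions(f[[2]], f[[1]], weights = c(spatial = 1, trace = 0))
  expect_false(anyDuplicated(m1$id_a) > 0)
  expect_false(anyDuplicated(m1$id_b) > 0)
  expect_setequal(paste(m1$id_a, m1$id_b), paste(m2$id_b, m2$id_a))
  expect_identical(m1, match_sessions(f[[1]], f[[2]],
                                      weights = c(spatial = 1, trace = 0)))
  expect_true(all(m1$score >= 0.5))
})

test_that("true correspondences survive dropout and centroid jitter", {
  hits <- total <- 0
  for (seed in 34:36) {
    cfg <- small_config(n = 120, seed = seed, dropout = 0.2)
    ex <- simulate_experiment(cfg, phases = c("habituation", "test"))
    f <- lapply(ex$sessions, function(s)
      feat(s$centroids$neuron_id,
           as.matrix(s$centroids[, c("x_um", "y_um")])))
    m <- match_sessions(f[[1]], f[[2]], weights = c(spatial = 1, trace = 0))
    common <- intersect(f[[1]]$neuron_ids, f[[2]]$neuron_ids)
    hits <- hits + sum(m$id_a == m$id_b)
    total <- total + length(common)
  }
  expect_gte(hits / total, 0.95)
})

test_that("empty sessions and missing features are rejected", {
  a <- feat(character(0))
  expect_error(match_sessions(a, a), "empty session")
  expect_error(match_sessions(feat("a"), feat("b")), "no feature")
})

test_that("category tracking preserves marginals and diagonal structure", {
  cls <- function(cats) {
    data.frame(neuron_id = sprintf("n%02d", seq_along(cats)),
               category = factor(cats, levels = c("increased", "no_change",
                                                  "decreased", "degenerate")),
               auc_post = seq_along(cats), stringsAsFactors = FALSE)
  }
  ids <- sprintf("n%02d", 1:12)
  tracked <- data.frame(s1 = ids, s2 = ids, s3 = ids)
  cats <- rep(c("increased", "no_change", "decreased"), each = 4)
  identical_cls <- list(habituation = cls(cats), cs2_cs1 = cls(cats),
                        test = cls(cats))
  trk <- track_categories(tracked, identical_cls)
  expect_equal(trk$n_tracked, 12L)
  expect_true(all(trk$transition[upper.tri(trk$transition)] == 0))
  expect_true(all(trk$transition[lower.tri(trk$transition)] == 0))
  # marginals equal per-phase category counts restricted to tracked neurons
  expect_equal(as.vector(rowSums(trk$transition)),
               as.vector(table(factor(cats, levels = rownames(trk$transition)))))

  # planted flip: unresponsive at habituation -> responsive at test
  flipped <- identical_cls
  flipped$test <- cls(rep("increased", 12))
  trk2 <- track_categories(tracked, flipped)
  expect_equal(unname(trk2$transition["no_change", "increased"]), 4L)
  expect_equal(unname(trk2$transition["decreased", "increased"]), 4L)
  expect_equal(sum(trk2$transition), 12L)
})

test_that("neurons missing a phase are dropped and counted", {
  ids <- sprintf("n%02d", 1:6)
  tracked <- data.frame(s1 = ids, s2 = ids)
  cl1 <- data.frame(neuron_id = ids, category = "no_change",
                    auc_post = 1, stringsAsFactors = FALSE)
  cl2 <- cl1[1:4, ]
  trk <- track_categories(tracked, list(habituation = cl1, test = cl2))
  expect_equal(trk$n_tracked, 4L)
  expect_equal(trk$n_dropped, 2L)
})

test_that("chained maps track only neurons present in every session", {
  m12 <- structure(data.frame(id_a = c("a1", "a2", "a3"),
                              id_b = c("b1", "b2", "b3"),
                              score = 1, stringsAsFactors = FALSE),
                   class = c("registration_map", "data.frame"))
  m23 <- structure(data.frame(id_a = c("b1", "b3"),
                              id_b = c("c1", "c3"),
                              score = 1, stringsAsFactors = FALSE),
                   class = c("registration_map", "data.frame"))
  chain <- chain_maps(list(m12, m23))
  expect_equal(chain$s1, c("a1", "a3"))
  expect_equal(chain$s3, c("c1", "c3"))
})
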
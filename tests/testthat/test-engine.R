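test_that("an empty stream yields unit evidence", {
  m <- make_conjugate_model()
  tr <- sgais_run(m, matrix(numeric(0), 0L, 1L),
                  sgais_config(seed = 81))
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$log_evidence, 0)
  expect_identical(tr$n_seen, 0L)
})

test_that("the running evidence matches the conjugate closed form", {
  m <- make_conjugate_model()
  set.seed(82)
  d <- simulate_dataset(m, 0.4, 200, seed = 83)
  # exact full-history gradients; a generous ensemble and a small step keep
  # discretization bias and weight-degeneracy noise inside the tolerance
  cfg <- sgais_config(n_particles = 100L, target_ess = 50, lr = 0.02,
                      burnin_steps = 30L, resample_policy = "ess",
                      chunk_size = 20L, batch_size = Inf, seed = 84)
  tr <- sgais_run(m, d, cfg)
  exact <- conjugate_log_evidence(d[, 1L])
  expect_lt(abs(tr$log_evidence[nrow(tr)] - exact), 0.5)
})

test_that("the trace telescopes and indexes predictives correctly", {
  m <- make_conjugate_model()
  d <- simulate_dataset(m, -0.2, 100, seed = 85)
  tr <- sgais_run(m, d, sgais_config(chunk_size = 25L, batch_size = Inf,
                                     seed = 86))
  expect_equal(sum(tr$predictive_logprob), tr$log_evidence[nrow(tr)],
               tolerance = 1e-10)
  expect_equal(predictive_log_prob(tr, 1L), tr$log_evidence[1L])
  expect_equal(predictive_log_prob(tr, 3L),
               tr$log_evidence[3L] - tr$log_evidence[2L])
  expect_error(predictive_log_prob(tr, 5L), "out of range")
  expect_true(all(diff(tr$n_seen) > 0))
})

test_that("chunk predictives track the conjugate predictive distribution", {
  m <- make_conjugate_model()
  d <- simulate_dataset(m, 0.9, 120, seed = 87)
  tr <- sgais_run(m, d, sgais_config(n_particles = 100L, target_ess = 50,
                                     lr = 0.02, burnin_steps = 30L,
                                     resample_policy = "ess",
                                     chunk_size = 40L, batch_size = Inf,
                                     seed = 88))
  for (k in 1:3) {
    exact_pred <- conjugate_log_evidence(d[seq_len(40 * k), 1L]) -
      conjugate_log_evidence(d[seq_len(40 * (k - 1)), 1L])
    expect_lt(abs(predictive_log_prob(tr, k) - exact_pred), 0.5)
  }
})

test_that("runs are reproducible under a seed", {
  m <- make_conjugate_model()
  d <- simulate_dataset(m, 0, 60, seed = 89)
  cfg <- sgais_config(chunk_size = 20L, seed = 90)
  expect_identical(as.data.frame(sgais_run(m, d, cfg)),
                   as.data.frame(sgais_run(m, d, cfg)))
})

test_that("the default configuration stays on the right evidence scale", {
  # reference defaults (10 particles, per-observation lr 0.1) trade accuracy
  # for speed; nat-scale error on a 10-chunk run is expected
  m <- make_conjugate_model()
  d <- simulate_dataset(m, 0.4, 200, seed = 91)
  exact <- conjugate_log_evidence(d[, 1L])
  for (policy in c("never", "ess")) {
    tr <- sgais_run(m, d, sgais_config(chunk_size = 20L, batch_size = Inf,
                                       resample_policy = policy, seed = 92))
    expect_lt(abs(tr$log_evidence[nrow(tr)] - exact), 3)
  }
})

test_that("reservoir fills deterministically below capacity and tracks the stream", {
  res <- reservoir(3L, 1L)
  for (x in 1:3) res <- reservoir_update(res, x)
  expect_equal(drop(res$records), c(1, 2, 3))
  expect_identical(res$stream_length, 3L)
  res <- reservoir_extend(res, matrix(4:10))
  expect_identical(res$stream_length, 10L)
  expect_identical(nrow(res$records), 3L)

  none <- reservoir(0L, 1L)
  none <- reservoir_extend(none, matrix(1:5))
  expect_identical(nrow(none$records), 0L)
  expect_identical(none$stream_length, 5L)
})

test_that("every stream element is retained with equal probability", {
  set.seed(93)
  cap <- 100L
  n <- 1000L
  reps <- 400L
  hits <- numeric(3)
  probe <- c(1L, 500L, 1000L)
  for (r in seq_len(reps)) {
    res <- reservoir_extend(reservoir(cap, 1L), matrix(seq_len(n)))
    hits <- hits + probe %in% res$records[, 1L]
  }
  p_hat <- hits / reps
  se <- sqrt(0.1 * 0.9 / reps)
  expect_true(all(abs(p_hat - cap / n) < 3.5 * se))
})

test_that("reservoir and exhaustive history modes agree in distribution", {
  m <- make_linreg_model()
  set.seed(94)
  d <- simulate_dataset(m, drop(m$sample_prior(1L)), 4000, seed = 95)
  exhaustive <- vapply(1:20, function(r) {
    tr <- sgais_run(m, d, sgais_config(seed = 200 + r))
    tr$log_evidence[nrow(tr)]
  }, numeric(1))
  reservoir <- vapply(1:20, function(r) {
    tr <- sgais_run(m, d, sgais_config(reservoir_capacity = 1000L,
                                       seed = 300 + r))
    tr$log_evidence[nrow(tr)]
  }, numeric(1))
  expect_gt(wilcox.test(exhaustive, reservoir)$p.value, 0.01)
})

test_that("a stationary stream raises no change-point flags", {
  # default chunk size: the default thresholds are calibrated for the
  # per-chunk noise at 500 observations per chunk
  m <- make_conjugate_model()
  d <- simulate_dataset(m, 0.5, 10000, seed = 96)
  tr <- sgais_run(m, d, sgais_config(seed = 97))
  expect_length(detect_shift(tr, window = 5L), 0L)
  expect_error(detect_shift(tr, window = 50L), "window")
})

test_that("replicate spread shrinks with more particles", {
  m <- make_conjugate_model()
  d <- simulate_dataset(m, 0.1, 150, seed = 98)
  spread <- function(M, seeds) {
    sd(vapply(seeds, function(s) {
      tr <- sgais_run(m, d, sgais_config(n_particles = M,
                                         target_ess = min(M / 2, 5),
                                         chunk_size = 30L,
                                         batch_size = Inf, seed = s))
      tr$log_evidence[nrow(tr)]
    }, numeric(1)))
  }
  set.seed(99)
  expect_lt(spread(40L, 1:12), spread(2L, 1:12))
})
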
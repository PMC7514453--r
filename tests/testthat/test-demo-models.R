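test_that("default demo models have 6, 44 and 25 parameters", {
  expect_identical(make_linreg_model()$dim, 6L)
  expect_identical(make_logreg_model()$dim, 44L)
  expect_identical(make_gmm_model()$dim, 25L)
  expect_identical(make_logreg_model(n_features = 1, n_classes = 2)$dim, 4L)
})

test_that("invalid model sizes are rejected", {
  expect_error(make_linreg_model(n_features = 0), "positive")
  expect_error(make_logreg_model(n_classes = 1), "at least 2")
  expect_error(make_gmm_model(n_components = 0), "positive")
})

test_that("prior draws are standard normal", {
  set.seed(51)
  th <- make_linreg_model()$sample_prior(10000L)
  expect_lt(abs(mean(th)), 0.02)
  expect_lt(abs(sd(th) - 1), 0.02)
})

test_that("linreg exact evidence handles the degenerate limits", {
  empty <- matrix(numeric(0), 0L, 2L)
  expect_identical(linreg_exact_log_evidence(empty), 0)
  set.seed(52)
  m <- make_linreg_model(n_features = 1, noise_sd = 0.8)
  recs <- simulate_dataset(m, c(0.5, -0.2), 7)
  expect_equal(
    linreg_exact_log_evidence(recs, noise_sd = 0.8, prior_sd = 0),
    sum(dnorm(recs[, 2L], 0, 0.8, log = TRUE)))
  expect_error(linreg_exact_log_evidence(recs, noise_sd = 0), "singular")
})

test_that("linreg exact evidence agrees with 2-d grid quadrature", {
  set.seed(53)
  m <- make_linreg_model(n_features = 1)
  recs <- simulate_dataset(m, c(0.8, -0.3), 5)
  quad <- quadrature_log_evidence_2d(m, recs)
  expect_equal(linreg_exact_log_evidence(recs), quad, tolerance = 1e-4)
})

test_that("linreg exact evidence matches a dense multivariate-normal oracle", {
  set.seed(54)
  m <- make_linreg_model(noise_sd = 1.4, prior_sd = 0.7)
  recs <- simulate_dataset(m, drop(m$sample_prior(1L)), 12)
  X <- cbind(recs[, 1:5], 1)
  y <- recs[, 6L]
  S <- 1.4^2 * diag(12) + 0.7^2 * tcrossprod(X)
  ch <- chol(S)
  oracle <- -0.5 * (12 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                      sum(backsolve(ch, y, transpose = TRUE)^2))
  expect_equal(linreg_exact_log_evidence(recs, 1.4, 0.7), oracle,
               tolerance = 1e-10)
})

test_that("logreg class probabilities are softmax-normalized", {
  m <- make_logreg_model(n_features = 3, n_classes = 4)
  set.seed(55)
  th <- m$sample_prior(2L)
  x <- rnorm(3)
  per_class <- sapply(1:4, function(k) {
    m$loglik_terms(th, matrix(c(x, k), nrow = 1L))
  }) # 2 particles x 4 classes
  expect_equal(apply(per_class, 1L, logsumexp), c(0, 0), tolerance = 1e-12)
})

test_that("gmm per-record density matches a naive mixture oracle", {
  m <- make_gmm_model(data_dim = 2, n_components = 3)
  set.seed(56)
  th <- drop(m$sample_prior(1L))
  recs <- matrix(rnorm(10), ncol = 2L)
  P <- matrix(th, nrow = 5L) # per component: mu(2), logvar(2), logit
  pi_k <- exp(P[5L, ] - logsumexp(P[5L, ]))
  oracle <- sapply(seq_len(nrow(recs)), function(i) {
    log(sum(sapply(1:3, function(k) {
      pi_k[k] * prod(dnorm(recs[i, ], P[1:2, k], exp(P[3:4, k] / 2)))
    })))
  })
  expect_equal(drop(m$loglik_terms(th, recs)), oracle, tolerance = 1e-12)
})

test_that("single-component gmm collapses to one Gaussian", {
  m <- make_gmm_model(data_dim = 2, n_components = 1)
  th <- c(0.5, -1, 0.2, -0.3, 1.7) # logit irrelevant: softmax of one is 1
  recs <- matrix(c(0.1, 0.4, -1, 2), ncol = 2L, byrow = TRUE)
  expected <- dnorm(recs[, 1L], 0.5, exp(0.1), log = TRUE) +
    dnorm(recs[, 2L], -1, exp(-0.15), log = TRUE)
  expect_equal(drop(m$loglik_terms(th, recs)), expected, tolerance = 1e-12)
})

test_that("gmm density integrates to 1 over a wide grid", {
  m <- make_gmm_model(data_dim = 2, n_components = 3)
  th <- c(-1, 0, 0, 0, 0.3, 1, 1, -0.2, 0.1, -0.4, 0, -1, 0.2, 0, 0.1)
  h <- 0.05
  g <- seq(-8 + h / 2, 8 - h / 2, by = h)
  grid <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  mass <- sum(exp(drop(m$loglik_terms(th, grid)))) * h^2
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("simulate_dataset is reproducible and respects N", {
  m <- make_linreg_model()
  th <- drop(m$sample_prior(1L))
  expect_identical(nrow(simulate_dataset(m, th, 0)), 0L)
  expect_error(simulate_dataset(m, th, -1), "nonnegative")
  a <- simulate_dataset(m, th, 50, seed = 7)
  b <- simulate_dataset(m, th, 50, seed = 7)
  expect_identical(a, b)
})

test_that("simulated linreg residual noise matches the model noise", {
  m <- make_linreg_model(noise_sd = 0.9)
  set.seed(57)
  th <- drop(m$sample_prior(1L))
  recs <- simulate_dataset(m, th, 1e5, seed = 58)
  resid <- recs[, 6L] - drop(recs[, 1:5] %*% th[1:5]) - th[6L]
  expect_lt(abs(sd(resid) / 0.9 - 1), 0.01)
})

test_that("shift stream has the stated phase structure", {
  spec <- shift_spec()
  expect_identical(spec$phase_sizes, c(1000L, 9000L, 90000L))
  d <- simulate_shift_dataset(spec, seed = 59)
  expect_identical(nrow(d), 100000L)
  lab <- attr(d, "cluster")
  expect_identical(sort(unique(lab[1:1000])), 1:3)
  expect_identical(sort(unique(lab[1001:10000])), 1:5)
  expect_identical(sort(unique(lab[10001:100000])), 1:7)
  # nesting: phase-1 clusters reappear later with identical centers
  expect_identical(attr(d, "phase"), rep(1:3, times = spec$phase_sizes))
})

test_that("shift_spec validates its arguments", {
  expect_error(shift_spec(cluster_counts = c(5, 3, 7)))
  d <- simulate_shift_dataset(shift_spec(scale = 0.01), seed = 60)
  expect_identical(nrow(d), 1000L)
})
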
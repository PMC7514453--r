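test_that("log_joint reduces to the prior on empty data and on a flat likelihood", {
  m <- make_conjugate_model()
  th <- matrix(c(-0.4, 0.7), nrow = 1L)
  empty <- matrix(numeric(0), 0L, 1L)
  expect_equal(log_joint(m, th, empty), m$log_prior(th))

  flat <- new_model("flat", 1L, 1L,
                    log_prior = m$log_prior,
                    grad_log_prior = m$grad_log_prior,
                    loglik_terms = function(theta, records) {
                      matrix(0, nrow(records), ncol(theta))
                    },
                    grad_loglik_sum = function(theta, records) {
                      matrix(0, 1L, ncol(theta))
                    },
                    sample_prior = m$sample_prior)
  recs <- matrix(c(1, 2, 3), ncol = 1L)
  expect_equal(log_joint(flat, th, recs), m$log_prior(th))
})

test_that("log_joint matches a direct Gaussian density computation", {
  m <- make_conjugate_model(noise_sd = 1.3, prior_sd = 2)
  y <- c(0.5, -1.2, 2.0)
  th <- 0.3
  expected <- dnorm(th, 0, 2, log = TRUE) +
    sum(dnorm(y, th, 1.3, log = TRUE))
  expect_equal(log_joint(m, th, matrix(y, ncol = 1L)), expected)
})

test_that("log_joint propagates -Inf terms and rejects dimension mismatches", {
  m <- make_conjugate_model()
  half <- new_model("half-support", 1L, 1L,
                    log_prior = m$log_prior,
                    grad_log_prior = m$grad_log_prior,
                    loglik_terms = function(theta, records) {
                      out <- matrix(0, nrow(records), ncol(theta))
                      out[records[, 1L] <= 0, ] <- -Inf
                      out
                    },
                    grad_loglik_sum = function(theta, records) {
                      matrix(0, 1L, ncol(theta))
                    },
                    sample_prior = m$sample_prior)
  expect_identical(log_joint(half, 0.1, matrix(c(1, -1), ncol = 1L)), -Inf)
  expect_error(log_joint(m, c(1, 2), matrix(1)), "parameters")
})

test_that("per-record log-likelihoods are additive over concatenation", {
  m <- make_linreg_model(n_features = 2)
  set.seed(41)
  th <- m$sample_prior(3L)
  a <- simulate_dataset(m, th[, 1L], 4, seed = 1)
  b <- simulate_dataset(m, th[, 1L], 3, seed = 2)
  both <- rbind(a, b)
  expect_equal(m$loglik_terms(th, both),
               rbind(m$loglik_terms(th, a), m$loglik_terms(th, b)))
  expect_equal(m$grad_loglik_sum(th, both),
               m$grad_loglik_sum(th, a) + m$grad_loglik_sum(th, b))
})

test_that("validate_model accepts correct gradients and flags a wrong sign", {
  set.seed(42)
  m <- make_linreg_model()
  recs <- simulate_dataset(m, drop(m$sample_prior(1L)), 30, seed = 5)
  rep_ok <- validate_model(m, recs)
  expect_true(rep_ok$ok)
  expect_lt(rep_ok$max_abs_diff, 1e-5)

  broken <- m
  broken$grad_loglik_sum <- function(theta, records) {
    -m$grad_loglik_sum(theta, records)
  }
  rep_bad <- validate_model(broken, recs)
  expect_false(rep_bad$ok)
  expect_identical(rep_bad$worst_component, "likelihood")
})

test_that("gradients of all three demo models pass finite-difference checks", {
  set.seed(43)
  for (m in list(make_linreg_model(), make_logreg_model(),
                 make_gmm_model())) {
    recs <- simulate_dataset(m, drop(m$sample_prior(1L)), 20)
    rep <- validate_model(m, recs, n_probes = 4L, tol = 1e-4)
    expect_true(rep$ok, info = m$name)
  }
})

test_that("a zero-parameter model is rejected", {
  expect_error(new_model("degenerate", 0L, 1L,
                         log_prior = identity, grad_log_prior = identity,
                         loglik_terms = identity, grad_loglik_sum = identity,
                         sample_prior = identity),
               "at least one parameter")
})

test_that("datasets round-trip through CSV with their manifest", {
  m <- make_linreg_model(n_features = 2)
  recs <- simulate_dataset(m, c(1, -1, 0.5), 10, seed = 9)
  path <- file.path(tempdir(), "roundtrip.csv")
  write_dataset(recs, path, manifest = list(seed = 9, n = 10))
  back <- read_dataset(path)
  expect_equal(unname(as.matrix(back[, ])), unname(recs[, ]),
               tolerance = 1e-12)
  expect_equal(attr(back, "manifest")$seed, 9)
  unlink(c(path, paste0(path, ".manifest.json")))
})
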
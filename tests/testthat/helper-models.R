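# Shared fixtures: a 1-d conjugate Gaussian-mean model with closed-form
# evidence, and grid-quadrature evidence oracles.

# y ~ N(mu, noise_sd^2), mu ~ N(0, prior_sd^2). The marginal of y_{1:n} is
# N(0, noise_sd^2 I + prior_sd^2 J), evaluated by Sherman-Morrison.
conjugate_log_evidence <- function(y, noise_sd = 1, prior_sd = 1) {
  n <- length(y)
  if (n == 0L) return(0)
  s2 <- noise_sd^2
  r2 <- prior_sd^2
  logdet <- (n - 1) * log(s2) + log(s2 + n * r2)
  quad <- sum(y^2) / s2 - r2 * sum(y)^2 / (s2 * (s2 + n * r2))
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

make_conjugate_model <- function(noise_sd = 1, prior_sd = 1) {
  s2 <- noise_sd^2
  new_model(
    name = "conjugate-mean", dim = 1L, record_width = 1L,
    log_prior = function(theta) {
      stats::dnorm(theta[1L, ], 0, prior_sd, log = TRUE)
    },
    grad_log_prior = function(theta) -theta / prior_sd^2,
    loglik_terms = function(theta, records) {
      mu <- matrix(theta[1L, ], nrow(records), ncol(theta), byrow = TRUE)
      matrix(stats::dnorm(records[, 1L], mu, noise_sd, log = TRUE),
             nrow(records))
    },
    grad_loglik_sum = function(theta, records) {
      y <- records[, 1L]
      matrix((sum(y) - nrow(records) * theta[1L, ]) / s2, nrow = 1L)
    },
    sample_prior = function(M) {
      matrix(stats::rnorm(M, sd = prior_sd), nrow = 1L)
    },
    simulate = function(theta, N) {
      matrix(stats::rnorm(N, mean = theta[1L], sd = noise_sd), ncol = 1L,
             dimnames = list(NULL, "y"))
    },
    exact_log_evidence = function(records) {
      conjugate_log_evidence(records[, 1L], noise_sd, prior_sd)
    })
}

# Brute-force evidence by midpoint quadrature on a 2-d parameter grid.
quadrature_log_evidence_2d <- function(model, records, lim = 6, h = 0.02) {
  g <- seq(-lim + h / 2, lim - h / 2, by = h)
  theta <- rbind(rep(g, times = length(g)), rep(g, each = length(g)))
  lp <- model$log_prior(theta)
  ll <- colSums(model$loglik_terms(theta, records))
  logsumexp(lp + ll) + 2 * log(h)
}
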
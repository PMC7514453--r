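#' Bayesian linear regression demonstration model
#'
#' Gaussian linear regression with known noise standard deviation: the
#' response is `y ~ Normal(x %*% w + b, noise_sd^2)` with standard-normal
#' covariates, independent `Normal(0, prior_sd^2)` priors on the weights and
#' intercept, and an analytically available marginal likelihood (the marginal
#' of `y` is a zero-mean Gaussian with covariance
#' `noise_sd^2 I + prior_sd^2 X X'`). The default has 5 covariate weights
#' plus an intercept, i.e. 6 parameters.
#'
#' Records have width `n_features + 1`: covariates then response. The
#' parameter vector stacks the weights first, intercept last.
#'
#' @param n_features Number of covariates (>= 1).
#' @param noise_sd Known observation noise standard deviation (> 0).
#' @param prior_sd Prior standard deviation on each parameter.
#' @return An [sgais_model][new_model] with `exact_log_evidence` set.
#' @export
make_linreg_model <- function(n_features = 5L, noise_sd = 1, prior_sd = 1) {
  n_features <- as.integer(n_features)
  if (is.na(n_features) || n_features < 1L) {
    stop("n_features must be a positive integer", call. = FALSE)
  }
  stopifnot(noise_sd > 0, prior_sd > 0)
  p <- n_features
  d <- p + 1L
  s2 <- noise_sd^2

  split_rec <- function(records) {
    list(X = records[, seq_len(p), drop = FALSE], y = records[, p + 1L])
  }
  # n x M matrix of means: covariate part plus per-particle intercept
  mean_matrix <- function(theta, X) {
    mu <- X %*% theta[seq_len(p), , drop = FALSE]
    sweep(mu, 2L, theta[d, ], "+")
  }

  new_model(
    name = sprintf("linreg-%dd", d),
    dim = d, record_width = p + 1L,
    log_prior = function(theta) {
      -0.5 * d * log(2 * pi * prior_sd^2) - colSums(theta^2) / (2 * prior_sd^2)
    },
    grad_log_prior = function(theta) -theta / prior_sd^2,
    loglik_terms = function(theta, records) {
      r <- split_rec(records)
      mu <- mean_matrix(theta, r$X)
      -0.5 * log(2 * pi * s2) - (r$y - mu)^2 / (2 * s2)
    },
    grad_loglik_sum = function(theta, records) {
      r <- split_rec(records)
      resid <- (r$y - mean_matrix(theta, r$X)) / s2 # n x M
      rbind(crossprod(r$X, resid), colSums(resid))
    },
    sample_prior = function(M) {
      matrix(stats::rnorm(d * M, sd = prior_sd), nrow = d, ncol = M)
    },
    simulate = function(theta, N) {
      X <- matrix(stats::rnorm(N * p), nrow = N, ncol = p)
      y <- drop(X %*% theta[seq_len(p)]) + theta[d] +
        stats::rnorm(N, sd = noise_sd)
      rec <- cbind(X, y)
      colnames(rec) <- c(paste0("x", seq_len(p)), "y")
      rec
    },
    exact_log_evidence = function(records) {
      linreg_exact_log_evidence(records, noise_sd = noise_sd,
                                prior_sd = prior_sd)
    },
    extra = list(n_features = p, noise_sd = noise_sd, prior_sd = prior_sd)
  )
}

#' Exact log marginal likelihood of the Gaussian linear regression model
#'
#' With a `Normal(0, prior_sd^2 I)` prior on the stacked (weights, intercept)
#' vector and known noise, the marginal distribution of the responses is
#' `y ~ Normal(0, noise_sd^2 I + prior_sd^2 X X')` where `X` is the design
#' matrix with an appended intercept column. The log density is evaluated via
#' the Woodbury/determinant-lemma identities so only a `(d x d)` system is
#' solved, making the computation linear in `N`. An empty dataset has
#' evidence 1 (log evidence 0).
#'
#' @param records Records as in [make_linreg_model()] (covariates then
#'   response), possibly zero rows.
#' @param noise_sd Observation noise standard deviation (> 0).
#' @param prior_sd Prior standard deviation (>= 0; 0 gives the point-mass
#'   prior at zero).
#' @return The exact log evidence (a single number).
#' @export
linreg_exact_log_evidence <- function(records, noise_sd = 1, prior_sd = 1) {
  if (noise_sd <= 0) {
    stop("noise_sd must be positive: the marginal covariance is singular",
         call. = FALSE)
  }
  records <- as_records(records)
  n <- nrow(records)
  if (n == 0L) return(0)
  p <- ncol(records) - 1L
  X <- cbind(records[, seq_len(p), drop = FALSE], 1)
  y <- records[, p + 1L]
  s2 <- noise_sd^2
  r2 <- prior_sd^2
  if (r2 == 0) return(sum(stats::dnorm(y, 0, noise_sd, log = TRUE)))
  d <- p + 1L
  A <- diag(d) + (r2 / s2) * crossprod(X)
  Xty <- crossprod(X, y)
  ch <- chol(A)
  logdetA <- 2 * sum(log(diag(ch)))
  quad <- (sum(y^2) - (r2 / s2) * sum(backsolve(ch, Xty, transpose = TRUE)^2)) / s2
  -0.5 * (n * log(2 * pi * s2) + logdetA + quad)
}

# Row-wise log-sum-exp of a matrix, used by the softmax models.
row_logsumexp <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  m + log(rowSums(exp(Z - m)))
}

#' Multiclass (softmax) logistic regression demonstration model
#'
#' Linear softmax classifier with one weight vector and bias per class and
#' independent standard-normal priors on all parameters. The default
#' (10 covariates, 4 classes) has `4 * 11 = 44` parameters. The model is
#' over-parameterized in the usual softmax sense; the prior regularizes the
#' redundant direction. Records have width `n_features + 1`: covariates then
#' a class label in `1..n_classes`.
#'
#' Parameter layout: class-major blocks of `(weights, bias)`.
#'
#' @param n_features Number of covariates (>= 1).
#' @param n_classes Number of classes (>= 2).
#' @param prior_sd Prior standard deviation on each parameter.
#' @return An [sgais_model][new_model]; no closed-form evidence.
#' @export
make_logreg_model <- function(n_features = 10L, n_classes = 4L, prior_sd = 1) {
  n_features <- as.integer(n_features)
  n_classes <- as.integer(n_classes)
  if (is.na(n_features) || n_features < 1L) {
    stop("n_features must be a positive integer", call. = FALSE)
  }
  if (is.na(n_classes) || n_classes < 2L) {
    stop("n_classes must be at least 2", call. = FALSE)
  }
  p <- n_features
  K <- n_classes
  d <- K * (p + 1L)

  # logits for one particle: n x K
  logits <- function(th, X) {
    W <- matrix(th, nrow = p + 1L, ncol = K) # per class: weights then bias
    X %*% W[seq_len(p), , drop = FALSE] +
      matrix(W[p + 1L, ], nrow(X), K, byrow = TRUE)
  }

  new_model(
    name = sprintf("logreg-%dc", K),
    dim = d, record_width = p + 1L,
    log_prior = function(theta) {
      -0.5 * d * log(2 * pi * prior_sd^2) - colSums(theta^2) / (2 * prior_sd^2)
    },
    grad_log_prior = function(theta) -theta / prior_sd^2,
    loglik_terms = function(theta, records) {
      X <- records[, seq_len(p), drop = FALSE]
      lab <- as.integer(records[, p + 1L])
      n <- nrow(X)
      out <- matrix(0, n, ncol(theta))
      for (m in seq_len(ncol(theta))) {
        Z <- logits(theta[, m], X)
        out[, m] <- Z[cbind(seq_len(n), lab)] - row_logsumexp(Z)
      }
      out
    },
    grad_loglik_sum = function(theta, records) {
      X <- records[, seq_len(p), drop = FALSE]
      lab <- as.integer(records[, p + 1L])
      n <- nrow(X)
      Y <- matrix(0, n, K)
      Y[cbind(seq_len(n), lab)] <- 1
      out <- matrix(0, d, ncol(theta))
      for (m in seq_len(ncol(theta))) {
        Z <- logits(theta[, m], X)
        P <- exp(Z - row_logsumexp(Z))
        E <- Y - P
        out[, m] <- as.vector(rbind(crossprod(X, E), colSums(E)))
      }
      out
    },
    sample_prior = function(M) {
      matrix(stats::rnorm(d * M, sd = prior_sd), nrow = d, ncol = M)
    },
    simulate = function(theta, N) {
      X <- matrix(stats::rnorm(N * p), nrow = N, ncol = p)
      Z <- logits(theta, X)
      P <- exp(Z - row_logsumexp(Z))
      lab <- vapply(seq_len(N), function(i) {
        sample.int(K, 1L, prob = P[i, ])
      }, integer(1L))
      rec <- cbind(X, lab)
      colnames(rec) <- c(paste0("x", seq_len(p)), "label")
      rec
    },
    extra = list(n_features = p, n_classes = K, prior_sd = prior_sd)
  )
}

#' Diagonal-covariance Gaussian mixture demonstration model
#'
#' Mixture of axis-aligned Gaussians on `data_dim`-dimensional observations.
#' Each component contributes `data_dim` means, `data_dim` log-variances and
#' one mixing logit (softmax-normalized across components), all with
#' independent standard-normal priors on the unconstrained scale; the default
#' (2-d data, 5 components) therefore has `5 * (2*2 + 1) = 25` parameters.
#'
#' Parameter layout: component-major blocks of
#' `(means, log_variances, logit)`.
#'
#' @param data_dim Dimension of an observation (>= 1).
#' @param n_components Number of mixture components (>= 1).
#' @param prior_sd Prior standard deviation on each unconstrained parameter.
#' @return An [sgais_model][new_model]; no closed-form evidence.
#' @export
make_gmm_model <- function(data_dim = 2L, n_components = 5L, prior_sd = 1) {
  data_dim <- as.integer(data_dim)
  K <- as.integer(n_components)
  if (is.na(data_dim) || data_dim < 1L) {
    stop("data_dim must be a positive integer", call. = FALSE)
  }
  if (is.na(K) || K < 1L) {
    stop("n_components must be a positive integer", call. = FALSE)
  }
  q <- data_dim
  blk <- 2L * q + 1L
  d <- K * blk

  unpack <- function(th) {
    P <- matrix(th, nrow = blk, ncol = K)
    list(mu = P[seq_len(q), , drop = FALSE],          # q x K
         logvar = P[q + seq_len(q), , drop = FALSE],  # q x K
         logit = P[blk, ])
  }
  # per-record per-component joint log density (log pi_k + log N_k): n x K
  comp_logdens <- function(pars, Yd) {
    n <- nrow(Yd)
    lpi <- pars$logit - logsumexp(pars$logit)
    out <- matrix(0, n, K)
    for (k in seq_len(K)) {
      v <- exp(pars$logvar[, k])
      dif <- sweep(Yd, 2L, pars$mu[, k], "-")
      out[, k] <- lpi[k] - 0.5 * sum(log(2 * pi * v)) -
        0.5 * drop(dif^2 %*% (1 / v))
    }
    out
  }

  new_model(
    name = sprintf("gmm-%dk", K),
    dim = d, record_width = q,
    log_prior = function(theta) {
      -0.5 * d * log(2 * pi * prior_sd^2) - colSums(theta^2) / (2 * prior_sd^2)
    },
    grad_log_prior = function(theta) -theta / prior_sd^2,
    loglik_terms = function(theta, records) {
      n <- nrow(records)
      out <- matrix(0, n, ncol(theta))
      for (m in seq_len(ncol(theta))) {
        out[, m] <- row_logsumexp(comp_logdens(unpack(theta[, m]), records))
      }
      out
    },
    grad_loglik_sum = function(theta, records) {
      out <- matrix(0, d, ncol(theta))
      for (m in seq_len(ncol(theta))) {
        pars <- unpack(theta[, m])
        ld <- comp_logdens(pars, records)
        R <- exp(ld - row_logsumexp(ld)) # responsibilities, n x K
        pi_k <- exp(pars$logit - logsumexp(pars$logit))
        G <- matrix(0, blk, K)
        for (k in seq_len(K)) {
          v <- exp(pars$logvar[, k])
          dif <- sweep(records, 2L, pars$mu[, k], "-")
          G[seq_len(q), k] <- crossprod(dif, R[, k]) / v
          G[q + seq_len(q), k] <-
            crossprod(dif^2, R[, k]) / (2 * v) - 0.5 * sum(R[, k])
          G[blk, k] <- sum(R[, k]) - pi_k[k] * nrow(records)
        }
        out[, m] <- as.vector(G)
      }
      out
    },
    sample_prior = function(M) {
      matrix(stats::rnorm(d * M, sd = prior_sd), nrow = d, ncol = M)
    },
    simulate = function(theta, N) {
      pars <- unpack(theta)
      pi_k <- exp(pars$logit - logsumexp(pars$logit))
      z <- sample.int(K, N, replace = TRUE, prob = pi_k)
      sd_k <- exp(pars$logvar / 2)
      rec <- t(pars$mu[, z, drop = FALSE] +
                 sd_k[, z, drop = FALSE] * matrix(stats::rnorm(q * N), q, N))
      colnames(rec) <- paste0("y", seq_len(q))
      rec
    },
    extra = list(data_dim = q, n_components = K, prior_sd = prior_sd)
  )
}

#' Simulate an i.i.d. dataset from a demonstration model
#'
#' Draws `N` independent records from the model's observation distribution at
#' fixed true parameters (covariates, where the model has them, are drawn
#' standard-normal). Runs are reproducible under `seed`.
#'
#' @param model An [sgais_model][new_model] providing a `simulate` field.
#' @param theta_true Parameter vector of length `model$dim`.
#' @param N Number of records (>= 0).
#' @param seed Optional integer seed.
#' @return An `N x record_width` records matrix with `theta_true` and `seed`
#'   attached as attributes.
#' @export
simulate_dataset <- function(model, theta_true, N, seed = NULL) {
  stopifnot(inherits(model, "sgais_model"))
  if (is.null(model$simulate)) {
    stop("model '", model$name, "' has no simulator", call. = FALSE)
  }
  N <- as.integer(N)
  if (is.na(N) || N < 0L) stop("N must be a nonnegative integer", call. = FALSE)
  theta_true <- drop(as_theta_matrix(theta_true, model$dim))
  if (!is.null(seed)) set.seed(seed)
  rec <- if (N == 0L) {
    matrix(numeric(0), nrow = 0L, ncol = model$record_width)
  } else {
    model$simulate(theta_true, N)
  }
  attr(rec, "theta_true") <- theta_true
  attr(rec, "seed") <- seed
  rec
}

#' Specification of the non-stationary clustered data stream
#'
#' Describes a 2-d stream whose generating distribution changes twice: the
#' first phase draws from 3 Gaussian clusters, the second from 5 (the
#' original 3 plus 2 new ones), the third from 7 (the previous 5 plus 2
#' more). Default phase sizes are 1000, 9000 and 90,000 observations, giving
#' a 100,000-record stream with change-points after observations 1000 and
#' 10,000. The `scale` argument shrinks every phase by a common factor for
#' quick experiments (e.g. `scale = 0.1` gives phases 100/900/9000).
#'
#' @param phase_sizes Integer vector of phase lengths.
#' @param cluster_counts Number of active clusters per phase; must be
#'   nondecreasing (each phase reuses all previous clusters).
#' @param data_dim Observation dimension.
#' @param scale Common multiplier applied to `phase_sizes`.
#' @return An object of class `shift_spec`.
#' @export
shift_spec <- function(phase_sizes = c(1000L, 9000L, 90000L),
                       cluster_counts = c(3L, 5L, 7L),
                       data_dim = 2L, scale = 1) {
  phase_sizes <- as.integer(round(phase_sizes * scale))
  cluster_counts <- as.integer(cluster_counts)
  stopifnot(length(phase_sizes) == length(cluster_counts),
            all(phase_sizes >= 1L), all(diff(cluster_counts) >= 0L),
            data_dim >= 1L)
  structure(list(phase_sizes = phase_sizes, cluster_counts = cluster_counts,
                 data_dim = as.integer(data_dim)),
            class = "shift_spec")
}

#' Simulate the non-stationary clustered stream
#'
#' Cluster centers for the final phase's full cluster set are drawn once from
#' a uniform box (with two centers deliberately placed close to earlier ones
#' so that some clusters overlap); all clusters have unit variance. Within
#' each phase, every record picks its cluster uniformly among that phase's
#' active clusters, so phase k's mixture nests phase k-1's components.
#'
#' @param spec A [shift_spec()].
#' @param seed Optional integer seed (fixes both the cluster geometry and the
#'   stream).
#' @return A records matrix with attributes `cluster` (per-record provenance
#'   label), `phase` (per-record phase index), `phase_sizes`, and `centers`.
#' @export
simulate_shift_dataset <- function(spec = shift_spec(), seed = NULL) {
  stopifnot(inherits(spec, "shift_spec"))
  if (!is.null(seed)) set.seed(seed)
  q <- spec$data_dim
  K <- max(spec$cluster_counts)
  centers <- matrix(stats::runif(K * q, -6, 6), nrow = K, ncol = q)
  # overlap: place one late cluster near an early one in each added batch
  if (K >= 4L) centers[4L, ] <- centers[1L, ] + 0.8
  if (K >= 6L) centers[6L, ] <- centers[2L, ] - 0.8
  N <- sum(spec$phase_sizes)
  lab <- integer(N)
  phase <- integer(N)
  pos <- 0L
  for (ph in seq_along(spec$phase_sizes)) {
    n_ph <- spec$phase_sizes[ph]
    idx <- pos + seq_len(n_ph)
    lab[idx] <- sample.int(spec$cluster_counts[ph], n_ph, replace = TRUE)
    phase[idx] <- ph
    pos <- pos + n_ph
  }
  rec <- centers[lab, , drop = FALSE] + matrix(stats::rnorm(N * q), N, q)
  colnames(rec) <- paste0("y", seq_len(q))
  attr(rec, "cluster") <- lab
  attr(rec, "phase") <- phase
  attr(rec, "phase_sizes") <- spec$phase_sizes
  attr(rec, "centers") <- centers
  rec
}
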
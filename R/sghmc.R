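#' SGHMC kernel configuration
#'
#' Parameters of the discretized underdamped Langevin update used as the
#' MCMC mutation kernel. One step maps `(theta, v)` to
#' `v' = v - eta * grad - alpha * v + N(0, 2 (alpha - beta_hat) eta)` and
#' `theta' = theta + v'` (velocity first, then position with the new
#' velocity). `eta` is the absolute learning rate of the discrete map; the
#' samplers in this package derive it from a per-observation rate divided by
#' the number of observations entering the potential, so that the step size
#' shrinks as the target sharpens.
#'
#' @param eta Learning rate (> 0).
#' @param alpha Momentum decay complement in (0, 1]; friction per step.
#' @param beta_hat Injected-noise offset in `[0, alpha]` accounting for
#'   gradient-noise variance; 0 ignores it (the gradient noise is
#'   `O(eta^2)` and vanishes relative to the `O(eta)` injected noise).
#' @param n_steps Number of kernel steps per invocation of [sghmc_run()].
#' @param batch_size Mini-batch size for the stochastic history gradient;
#'   `Inf` uses the whole history (exact full-data gradients).
#' @return A list of class `sghmc_config`.
#' @export
sghmc_config <- function(eta, alpha = 0.2, beta_hat = 0,
                         n_steps = 20L, batch_size = 500L) {
  stopifnot(eta > 0, alpha > 0, alpha <= 1,
            beta_hat >= 0, alpha - beta_hat >= 0,
            n_steps >= 1L, batch_size >= 1)
  structure(list(eta = eta, alpha = alpha, beta_hat = beta_hat,
                 n_steps = as.integer(n_steps), batch_size = batch_size),
            class = "sghmc_config")
}

#' Annealed stochastic potential over a data chunk and its history
#'
#' Describes the tempered partial-data target whose negative log density is
#' the potential energy: `lambda` times the log-likelihood of the current
#' chunk, plus the log-likelihood of all previously absorbed observations,
#' plus the log prior. The history term is estimated stochastically by
#' scaling a mini-batch drawn with replacement from `history` (the exhaustive
#' store or a reservoir) by `n_prev / |B|`.
#'
#' @param model An [sgais_model][new_model].
#' @param chunk Records of the current chunk (`n x record_width` matrix).
#' @param lambda Inverse temperature in `[0, 1]` applied to the chunk term.
#' @param history Matrix of available past records (possibly a uniform
#'   reservoir subsample of the stream).
#' @param n_prev Number of past observations the history represents.
#' @param n_hist Number of leading rows of `history` that are valid source
#'   records (defaults to all of them); lets a caller hand over a
#'   preallocated buffer without copying.
#' @return A list of class `potential_spec`.
#' @export
potential_spec <- function(model, chunk, lambda, history = NULL,
                           n_prev = 0L,
                           n_hist = if (is.null(history)) 0L
                                    else nrow(history)) {
  stopifnot(lambda >= 0, lambda <= 1, n_prev >= 0)
  if (n_prev > 0 && n_hist == 0L) {
    stop("history records are required when n_prev > 0", call. = FALSE)
  }
  structure(list(model = model, chunk = as_records(chunk, model$record_width),
                 lambda = lambda, history = history, n_prev = n_prev,
                 n_hist = as.integer(n_hist)),
            class = "potential_spec")
}

#' Stochastic gradient of the annealed potential
#'
#' Returns the `dim x M` matrix
#' `-lambda * grad loglik(chunk) - (n_prev/|B|) * grad loglik(batch)
#'  - grad log prior`,
#' an unbiased estimate (over batch draws) of the gradient of the potential
#' described by `pot`. With `n_prev = 0` the history term is omitted; with
#' `batch` equal to the full history the estimate is exact.
#'
#' @param pot A [potential_spec()].
#' @param theta `dim x M` particle matrix (or a single parameter vector).
#' @param batch Mini-batch of history records drawn i.i.d. with replacement,
#'   or `NULL` when `pot$n_prev == 0`.
#' @return `dim x M` gradient matrix of the potential (note the sign: this
#'   is the negative gradient of the log target).
#' @export
stochastic_potential_grad <- function(pot, theta, batch = NULL) {
  model <- pot$model
  theta <- as_theta_matrix(theta, model$dim)
  g <- -model$grad_log_prior(theta)
  if (pot$lambda > 0 && nrow(pot$chunk) > 0L) {
    g <- g - pot$lambda * model$grad_loglik_sum(theta, pot$chunk)
  }
  if (pot$n_prev > 0L) {
    if (is.null(batch) || nrow(batch) == 0L) {
      stop("a non-empty mini-batch is required when n_prev > 0",
           call. = FALSE)
    }
    g <- g - (pot$n_prev / nrow(batch)) * model$grad_loglik_sum(theta, batch)
  }
  g
}

#' One SGHMC transition
#'
#' Semi-implicit Euler update: the velocity absorbs the gradient, friction
#' and injected noise first, then the position moves by the new velocity.
#' With `beta_hat == alpha` the noise scale is zero and the map is
#' deterministic given `(theta, v, grad)`.
#'
#' @param theta,v `dim x M` position and velocity matrices.
#' @param grad `dim x M` potential gradient (from
#'   [stochastic_potential_grad()]).
#' @param cfg An [sghmc_config()].
#' @return List with updated `theta` and `v`.
#' @export
sghmc_step <- function(theta, v, grad, cfg) {
  if (anyNA(grad) || any(!is.finite(grad))) {
    bad <- which(colSums(!is.finite(grad)) > 0L)
    stop("non-finite potential gradient for particle(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  noise_sd <- sqrt(2 * (cfg$alpha - cfg$beta_hat) * cfg$eta)
  v <- v - cfg$eta * grad - cfg$alpha * v
  if (noise_sd > 0) {
    v <- v + noise_sd * matrix(stats::rnorm(length(v)), nrow(v), ncol(v))
  }
  theta <- theta + v
  list(theta = theta, v = v)
}

#' Run a sequence of SGHMC transitions under a stochastic potential
#'
#' Applies `cfg$n_steps` transitions, drawing a fresh history mini-batch
#' (uniformly with replacement) before each one; velocities persist across
#' steps within the run.
#'
#' @param theta,v `dim x M` position and velocity matrices.
#' @param pot A [potential_spec()].
#' @param cfg An [sghmc_config()].
#' @return List with final `theta`, `v`, and `grad_evals`, the number of
#'   per-record gradient term evaluations performed (a hardware-independent
#'   cost measure).
#' @export
sghmc_run <- function(theta, v, pot, cfg) {
  n_hist <- pot$n_hist
  use_full <- pot$n_prev > 0L &&
    (!is.finite(cfg$batch_size) || cfg$batch_size >= n_hist)
  b <- if (pot$n_prev > 0L && !use_full) as.integer(cfg$batch_size) else n_hist
  per_step <- (nrow(pot$chunk) + if (pot$n_prev > 0L) b else 0L) * ncol(theta)
  for (s in seq_len(cfg$n_steps)) {
    batch <- if (pot$n_prev == 0L) {
      NULL
    } else if (use_full) {
      pot$history[seq_len(n_hist), , drop = FALSE]
    } else {
      pot$history[sample.int(n_hist, b, replace = TRUE), , drop = FALSE]
    }
    g <- stochastic_potential_grad(pot, theta, batch)
    st <- sghmc_step(theta, v, g, cfg)
    theta <- st$theta
    v <- st$v
  }
  list(theta = theta, v = v, grad_evals = per_step * cfg$n_steps)
}
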
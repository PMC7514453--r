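#' Sigmoidal annealing schedule
#'
#' The fixed schedule used by vanilla AIS: `lambda_t = sigma(delta *
#' (2 t / T - 1))`, affinely rescaled so that `lambda_0 = 0` and
#' `lambda_T = 1` exactly (the logistic function never attains 0 or 1). As
#' `delta -> 0` the schedule tends to linear; larger `delta` concentrates
#' steps near both ends, where the tempered target changes fastest.
#'
#' @param n_temps Number of temperature increments `T` (>= 1); the schedule
#'   has `T + 1` points.
#' @param delta Sharpness of the sigmoid (> 0).
#' @return Strictly increasing numeric vector `lambda_0 ... lambda_T`.
#' @export
sigmoid_schedule <- function(n_temps, delta = 4) {
  stopifnot(n_temps >= 1L, delta > 0)
  t <- 0:n_temps
  raw <- stats::plogis(delta * (2 * t / n_temps - 1))
  (raw - raw[1L]) / (raw[n_temps + 1L] - raw[1L])
}

#' Vanilla AIS configuration
#'
#' Matches the sequential sampler's kernel settings but uses the whole
#' dataset for every gradient and weight update: `M = 10` particles,
#' 20 SGHMC steps per intermediate distribution, per-observation learning
#' rate 0.1 (kernel step `lr / N`), `alpha = 0.2`, `beta_hat = 0`, and a
#' sigmoidal schedule.
#'
#' @param n_temps Number of intermediate distributions `T`.
#' @param delta Sigmoid sharpness for [sigmoid_schedule()].
#' @param n_particles Number of particles.
#' @param steps_per_temp SGHMC steps per intermediate distribution.
#' @param lr Per-observation learning rate.
#' @param alpha,beta_hat SGHMC friction and noise offset.
#' @param seed Optional integer seed.
#' @return A list of class `ais_config`.
#' @export
ais_config <- function(n_temps = 100L, delta = 4, n_particles = 10L,
                       steps_per_temp = 20L, lr = 0.1, alpha = 0.2,
                       beta_hat = 0, seed = NULL) {
  stopifnot(n_temps >= 1L, n_particles >= 1L, steps_per_temp >= 0L, lr > 0)
  structure(list(n_temps = as.integer(n_temps), delta = delta,
                 n_particles = as.integer(n_particles),
                 steps_per_temp = as.integer(steps_per_temp),
                 lr = lr, alpha = alpha, beta_hat = beta_hat, seed = seed),
            class = "ais_config")
}

#' Annealed importance sampling over the full dataset
#'
#' Reference estimator: particles start at the prior; at each step of the
#' fixed sigmoidal schedule the importance weights are multiplied by the
#' full-data likelihood to the power of the increment, then each particle is
#' mutated by SGHMC targeting `p(D | theta)^lambda p(theta)` with exact
#' full-data gradients. The weight update uses the particle positions from
#' before the mutation. The estimator is unbiased for the evidence.
#'
#' @param model An [sgais_model][new_model].
#' @param data Records matrix (non-empty).
#' @param cfg An [ais_config()].
#' @return List with `log_evidence` (log mean final weight), `log_weights`,
#'   `schedule`, and `grad_evals`.
#' @export
ais_run <- function(model, data, cfg = ais_config()) {
  stopifnot(inherits(model, "sgais_model"), inherits(cfg, "ais_config"))
  data <- as_records(data, model$record_width)
  if (nrow(data) == 0L) stop("data must be non-empty", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  N <- nrow(data)
  M <- cfg$n_particles
  lambda <- sigmoid_schedule(cfg$n_temps, cfg$delta)
  theta <- model$sample_prior(M)
  v <- matrix(0, model$dim, M)
  lw <- rep(0, M)
  kcfg <- sghmc_config(eta = cfg$lr / N, alpha = cfg$alpha,
                       beta_hat = cfg$beta_hat,
                       n_steps = max(cfg$steps_per_temp, 1L),
                       batch_size = Inf)
  grad_evals <- 0
  ll <- sum_loglik(model$loglik_terms(theta, data))
  for (t in seq_len(cfg$n_temps)) {
    lw <- lw + (lambda[t + 1L] - lambda[t]) * ll
    if (cfg$steps_per_temp > 0L) {
      pot <- potential_spec(model, data, lambda[t + 1L])
      run <- sghmc_run(theta, v, pot, kcfg)
      theta <- run$theta
      v <- run$v
      grad_evals <- grad_evals + run$grad_evals
    }
    if (t < cfg$n_temps) ll <- sum_loglik(model$loglik_terms(theta, data))
  }
  if (all(lw == -Inf)) {
    stop("degenerate AIS run: all importance weights are zero",
         call. = FALSE)
  }
  list(log_evidence = logmeanexp(lw), log_weights = lw,
       schedule = lambda, grad_evals = grad_evals)
}

#' Nested sampling configuration
#'
#' Defaults follow the reference baseline: 2 live points, 20 SGHMC steps on
#' the prior potential per constrained draw (step size `1e-3`, friction
#' `alpha = 0.1`, no noise offset — there is no gradient noise when
#' sampling from the prior), and termination when the latest additive
#' contribution falls below 1% of the running evidence estimate.
#'
#' @param n_live Number of live points (>= 2).
#' @param constrained_steps SGHMC steps per constrained-prior draw.
#' @param eta Absolute SGHMC step size on the prior potential.
#' @param alpha,beta_hat SGHMC friction and noise offset.
#' @param stop_fraction Termination threshold as a fraction of the running
#'   evidence.
#' @param max_iter Safety cap on iterations.
#' @param seed Optional integer seed.
#' @return A list of class `ns_config`.
#' @export
ns_config <- function(n_live = 2L, constrained_steps = 20L, eta = 1e-3,
                      alpha = 0.1, beta_hat = 0, stop_fraction = 0.01,
                      max_iter = 100000L, seed = NULL) {
  stopifnot(n_live >= 2L, constrained_steps >= 1L, eta > 0,
            stop_fraction > 0, stop_fraction < 1)
  structure(list(n_live = as.integer(n_live),
                 constrained_steps = as.integer(constrained_steps),
                 eta = eta, alpha = alpha, beta_hat = beta_hat,
                 stop_fraction = stop_fraction,
                 max_iter = as.integer(max_iter), seed = seed),
            class = "ns_config")
}

#' Nested sampling over the full dataset
#'
#' Reference estimator: live points are drawn from the prior; at each
#' iteration the lowest-likelihood point is recorded as a dead point with
#' prior-volume weight `X_{k-1} - X_k` (deterministic shrinkage
#' `X_k = exp(-k / n_live)`) and replaced by a constrained-prior draw: SGHMC
#' on the prior potential started from a surviving live point, with any move
#' whose full-data likelihood does not exceed the dead point's likelihood
#' rejected (position restored, velocity reflected — a bounce off the
#' likelihood contour, which keeps the chain's stationary distribution close
#' to the constrained prior instead of letting it pile up at the boundary).
#' The loop stops when the
#' latest contribution is below `stop_fraction` of the running evidence,
#' after which the remaining live points contribute `L_i X_K / n_live`.
#'
#' @param model An [sgais_model][new_model].
#' @param data Records matrix (non-empty).
#' @param cfg An [ns_config()].
#' @return List with `log_evidence`, `iterations`, `dead_logliks` (the
#'   nondecreasing sequence of dead-point log-likelihoods), `stalled` (number
#'   of replacement draws that never moved), and `grad_evals`.
#' @export
ns_run <- function(model, data, cfg = ns_config()) {
  stopifnot(inherits(model, "sgais_model"), inherits(cfg, "ns_config"))
  data <- as_records(data, model$record_width)
  if (nrow(data) == 0L) stop("data must be non-empty", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_live <- cfg$n_live
  theta <- model$sample_prior(n_live)
  live_ll <- sum_loglik(model$loglik_terms(theta, data))
  log_shrink_w <- function(k) {
    -(k - 1) / n_live + log(1 - exp(-1 / n_live))
  }
  logZ <- -Inf
  dead <- numeric(0)
  stalled <- 0L
  grad_evals <- 0
  k <- 0L
  repeat {
    k <- k + 1L
    worst <- which.min(live_ll)
    Lstar <- live_ll[worst]
    contrib <- Lstar + log_shrink_w(k)
    logZ <- logsumexp(c(logZ, contrib))
    dead[k] <- Lstar
    # constrained-prior replacement draw
    start <- if (n_live > 2L) {
      sample(setdiff(seq_len(n_live), worst), 1L)
    } else {
      setdiff(seq_len(n_live), worst)[1L]
    }
    th <- theta[, start, drop = FALSE]
    ll <- live_ll[start]
    vv <- matrix(0, model$dim, 1L)
    moved <- FALSE
    noise_sd <- sqrt(2 * (cfg$alpha - cfg$beta_hat) * cfg$eta)
    for (s in seq_len(cfg$constrained_steps)) {
      g <- -model$grad_log_prior(th)
      v_new <- vv - cfg$eta * g - cfg$alpha * vv +
        noise_sd * matrix(stats::rnorm(model$dim), model$dim, 1L)
      th_new <- th + v_new
      ll_new <- sum_loglik(model$loglik_terms(th_new, data))
      grad_evals <- grad_evals + nrow(data)
      if (ll_new > Lstar) {
        th <- th_new
        vv <- v_new
        ll <- ll_new
        moved <- TRUE
      } else {
        vv <- -v_new
      }
    }
    if (!moved) stalled <- stalled + 1L
    theta[, worst] <- th
    live_ll[worst] <- ll
    # stop when the live set's best remaining mass is negligible
    remaining <- max(live_ll) - k / n_live
    if (remaining < log(cfg$stop_fraction) + logZ || k >= cfg$max_iter) break
  }
  final <- live_ll - k / n_live - log(n_live)
  logZ <- logsumexp(c(logZ, final))
  list(log_evidence = logZ, iterations = k, dead_logliks = dead,
       stalled = stalled, grad_evals = grad_evals)
}
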
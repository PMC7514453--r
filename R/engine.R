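#' SGAIS run configuration
#'
#' Defaults follow the reference experimental setup: chunks of 500
#' observations absorbed per Bayesian-updating step, mini-batches of the same
#' size for the stochastic history gradient, 10 particles, a target ESS of 5
#' for the adaptive annealing schedule, 20 SGHMC burn-in steps per
#' intermediate distribution, per-observation learning rate 0.1 (the kernel
#' step size is `lr / n` with `n` the observations absorbed so far, so the
#' step shrinks as the posterior sharpens), momentum decay complement
#' `alpha = 0.2` and noise offset `beta_hat = 0`.
#'
#' @param n_particles Number of particles `M`.
#' @param target_ess Target effective sample size in `[1, M]` for
#'   [find_delta()].
#' @param chunk_size Observations absorbed per Bayesian-updating step.
#' @param burnin_steps SGHMC steps per intermediate distribution.
#' @param lr Per-observation learning rate.
#' @param alpha,beta_hat SGHMC friction and noise-offset parameters.
#' @param batch_size History mini-batch size; `Inf` for exact full-history
#'   gradients.
#' @param resample_policy `"never"` (default) or `"ess"`: systematic
#'   resampling before each mutation whenever the cumulative-weight ESS
#'   falls below `M / 2`. With few particles resampling risks mode collapse,
#'   hence the conservative default.
#' @param reservoir_capacity If non-`NULL`, keep only a uniform reservoir of
#'   this many past records (streaming mode) instead of the exhaustive
#'   history store.
#' @param seed Optional integer seed; per-chunk subseeds are derived from it
#'   deterministically.
#' @return A list of class `sgais_config`.
#' @export
sgais_config <- function(n_particles = 10L, target_ess = 5,
                         chunk_size = 500L, burnin_steps = 20L,
                         lr = 0.1, alpha = 0.2, beta_hat = 0,
                         batch_size = 500L,
                         resample_policy = c("never", "ess"),
                         reservoir_capacity = NULL, seed = NULL) {
  resample_policy <- match.arg(resample_policy)
  stopifnot(n_particles >= 1L, target_ess >= 1, target_ess <= n_particles,
            chunk_size >= 1L, burnin_steps >= 0L, lr > 0, batch_size >= 1)
  structure(list(n_particles = as.integer(n_particles),
                 target_ess = target_ess,
                 chunk_size = as.integer(chunk_size),
                 burnin_steps = as.integer(burnin_steps),
                 lr = lr, alpha = alpha, beta_hat = beta_hat,
                 batch_size = batch_size,
                 resample_policy = resample_policy,
                 reservoir_capacity = reservoir_capacity,
                 seed = seed),
            class = "sgais_config")
}

#' Online evidence estimation by stochastic gradient annealed importance
#' sampling
#'
#' Runs the sequential estimator: particles start at the prior with unit
#' weights; each chunk of observations is absorbed through an adaptive
#' annealing schedule that raises the chunk likelihood's power from 0 to 1,
#' multiplying the importance weights by the chunk likelihood to the power of
#' each increment (chosen by [find_delta()] to hold the incremental-weight
#' ESS at the target) and mutating every particle with SGHMC steps whose
#' potential combines the tempered chunk, a mini-batch estimate of the
#' absorbed history, and the prior. After each chunk the running log-evidence
#' is the log mean weight, and its increment over the previous chunk is the
#' chunk's predictive log-probability.
#'
#' @param model An [sgais_model][new_model].
#' @param data Records matrix (observations in stream order).
#' @param cfg An [sgais_config()].
#' @return An `sgais_trace`: a data frame with one row per chunk and columns
#'   `n_seen`, `log_evidence`, `annealing_steps` (intermediate distributions
#'   used, i.e. schedule steps beyond the final jump to 1),
#'   `predictive_logprob`, and `cum_grad_evals`; the configuration and final
#'   ensemble are attached as attributes `"config"` and `"ensemble"`.
#' @export
sgais_run <- function(model, data, cfg = sgais_config()) {
  stopifnot(inherits(model, "sgais_model"), inherits(cfg, "sgais_config"))
  data <- as_records(data, model$record_width)
  N <- nrow(data)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  M <- cfg$n_particles
  ens <- particle_ensemble(model$sample_prior(M))

  n_chunks <- if (N == 0L) 0L else ceiling(N / cfg$chunk_size)
  trace <- data.frame(n_seen = integer(n_chunks),
                      log_evidence = numeric(n_chunks),
                      annealing_steps = integer(n_chunks),
                      predictive_logprob = numeric(n_chunks),
                      cum_grad_evals = numeric(n_chunks))
  if (N == 0L) {
    trace <- data.frame(n_seen = 0L, log_evidence = 0,
                        annealing_steps = 0L,
                        predictive_logprob = NA_real_, cum_grad_evals = 0)
    return(finish_trace(trace, cfg, ens, model))
  }

  use_reservoir <- !is.null(cfg$reservoir_capacity)
  if (use_reservoir) {
    res <- reservoir(cfg$reservoir_capacity, model$record_width)
  }
  n_prev <- 0L
  grad_evals <- 0
  prev_logZ <- 0
  for (k in seq_len(n_chunks)) {
    if (!is.null(cfg$seed)) set.seed(derive_seed(cfg$seed, k))
    chunk <- data[(n_prev + 1L):min(n_prev + cfg$chunk_size, N), ,
                  drop = FALSE]
    n_now <- n_prev + nrow(chunk)
    kcfg <- sghmc_config(eta = cfg$lr / n_now, alpha = cfg$alpha,
                         beta_hat = cfg$beta_hat,
                         n_steps = max(cfg$burnin_steps, 1L),
                         batch_size = cfg$batch_size)
    # exhaustive mode reads past rows of `data` in place; reservoir mode
    # reads the uniform subsample
    hist_rec <- if (use_reservoir) res$records else data
    n_hist <- if (use_reservoir) nrow(res$records) else n_prev
    # fresh momenta for the chunk's annealing sequence
    ens$v[] <- 0
    lambda <- 0
    steps <- 0L
    chunk_ll <- sum_loglik(model$loglik_terms(ens$theta, chunk))
    repeat {
      delta <- find_delta(chunk_ll, lambda, cfg$target_ess)
      lambda <- min(lambda + delta, 1)
      ens <- update_weights(ens, chunk_ll, delta)
      if (cfg$resample_policy == "ess" && ess(ens$log_weights) < M / 2) {
        ens <- resample(ens)
      }
      if (cfg$burnin_steps > 0L) {
        pot <- potential_spec(model, chunk, lambda, hist_rec, n_prev,
                              n_hist)
        run <- sghmc_run(ens$theta, ens$v, pot, kcfg)
        ens$theta <- run$theta
        ens$v <- run$v
        grad_evals <- grad_evals + run$grad_evals
      }
      steps <- steps + 1L
      if (lambda >= 1) break
      chunk_ll <- sum_loglik(model$loglik_terms(ens$theta, chunk))
    }
    logZ <- logmeanexp(ens$log_weights)
    trace$n_seen[k] <- n_now
    trace$log_evidence[k] <- logZ
    trace$annealing_steps[k] <- steps - 1L
    trace$predictive_logprob[k] <- logZ - prev_logZ
    trace$cum_grad_evals[k] <- grad_evals
    prev_logZ <- logZ
    if (use_reservoir) res <- reservoir_extend(res, chunk)
    n_prev <- n_now
  }
  finish_trace(trace, cfg, ens, model)
}

finish_trace <- function(trace, cfg, ens, model) {
  attr(trace, "config") <- cfg
  attr(trace, "ensemble") <- ens
  attr(trace, "model_name") <- model$name
  class(trace) <- c("sgais_trace", "data.frame")
  trace
}

#' @export
print.sgais_trace <- function(x, ...) {
  cat("<sgais_trace> ", attr(x, "model_name"), ": ", nrow(x),
      " chunk(s), n = ", max(x$n_seen), ", log Z = ",
      format(x$log_evidence[nrow(x)], digits = 6), "\n", sep = "")
  NextMethod()
}

#' Plot an evidence trace
#'
#' Draws the per-observation log-evidence and the per-chunk annealing effort
#' against the number of observations seen.
#'
#' @param x An `sgais_trace` from [sgais_run()].
#' @param ... Passed to [plot()].
#' @export
plot.sgais_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  keep <- x$n_seen > 0
  graphics::plot(x$n_seen[keep], x$log_evidence[keep] / x$n_seen[keep],
                 type = "l", xlab = "observations",
                 ylab = "log Z / n", ...)
  graphics::plot(x$n_seen[keep], x$annealing_steps[keep], type = "h",
                 xlab = "observations", ylab = "annealing steps")
  invisible(x)
}

#' Predictive log-probability of a chunk
#'
#' The evidence factorizes into predictive probabilities, so the chunk's
#' predictive log-probability is the increment of the running log-evidence:
#' `log Z(k) - log Z(k-1)` with `log Z(0) = 0`.
#'
#' @param trace An `sgais_trace`.
#' @param k Chunk index (1-based).
#' @return The chunk's predictive log-probability.
#' @export
predictive_log_prob <- function(trace, k) {
  rows <- trace[trace$n_seen > 0, , drop = FALSE]
  if (k < 1 || k > nrow(rows)) {
    stop("chunk index out of range", call. = FALSE)
  }
  prev <- if (k == 1L) 0 else rows$log_evidence[k - 1L]
  rows$log_evidence[k] - prev
}

#' Uniform reservoir over a record stream
#'
#' Classic single-pass reservoir sampling: the first `capacity` records fill
#' the reservoir; each later record replaces a uniformly chosen slot with
#' probability `capacity / stream_length`, so every past record is retained
#' with equal probability. Used to mini-batch over unbounded history in
#' streaming mode.
#'
#' @param capacity Maximum number of stored records (>= 0).
#' @param record_width Number of columns of a record.
#' @return An empty `sgais_reservoir`.
#' @export
reservoir <- function(capacity, record_width) {
  capacity <- as.integer(capacity)
  stopifnot(capacity >= 0L)
  structure(list(capacity = capacity,
                 records = matrix(numeric(0), 0L, record_width),
                 stream_length = 0L),
            class = "sgais_reservoir")
}

#' @describeIn reservoir Offer one record to the reservoir.
#' @param res An `sgais_reservoir`.
#' @param record A single record (numeric vector).
#' @export
reservoir_update <- function(res, record) {
  reservoir_extend(res, matrix(record, nrow = 1L))
}

#' @describeIn reservoir Offer a block of records (one per row) in stream
#'   order.
#' @param records Records matrix.
#' @export
reservoir_extend <- function(res, records) {
  records <- as_records(records, ncol(res$records))
  n <- nrow(records)
  if (n == 0L) return(res)
  cap <- res$capacity
  t0 <- res$stream_length
  i <- 1L
  if (cap > 0L && nrow(res$records) < cap) {
    take <- min(cap - nrow(res$records), n)
    res$records <- rbind(res$records, records[seq_len(take), , drop = FALSE])
    i <- take + 1L
  }
  if (i <= n && cap > 0L) {
    idx <- i:n
    u <- stats::runif(length(idx)) * (t0 + idx)
    hit <- which(u < cap)
    for (h in hit) {
      res$records[max(1L, ceiling(u[h])), ] <- records[idx[h], ]
    }
  }
  res$stream_length <- t0 + n
  res
}

#' Flag change-points in an evidence trace
#'
#' A shift in the data-generating distribution shows up as a drop in the
#' per-observation predictive log-probability and as a spike in the
#' annealing effort. Under a stationary stream the predictive improves as
#' the posterior concentrates, so each chunk is compared against the best
#' (maximum) per-observation predictive over the preceding `window` chunks;
#' a chunk is flagged when it falls more than `pred_drop` below that
#' recent-best level, or when its annealing-step count exceeds the
#' window's median by more than `step_spike`. Chunks from index 2 onward
#' are assessed (the baseline is truncated while fewer than `window`
#' predecessors exist). Default thresholds are calibrated so that a
#' stationary stream at the default chunk size produces no flags with a
#' severalfold margin.
#'
#' @param trace An `sgais_trace`.
#' @param window Number of preceding chunks forming the rolling baseline.
#' @param pred_drop Drop threshold, in nats per observation.
#' @param step_spike Annealing-step excess threshold, in steps.
#' @return Integer vector of flagged chunk indices (possibly empty).
#' @export
detect_shift <- function(trace, window = 5L, pred_drop = 0.4,
                         step_spike = 3) {
  rows <- trace[trace$n_seen > 0, , drop = FALSE]
  n_chunks <- nrow(rows)
  if (n_chunks <= window) {
    stop("trace has ", n_chunks, " chunk(s); need more than window = ",
         window, call. = FALSE)
  }
  sizes <- diff(c(0L, rows$n_seen))
  per_obs <- rows$predictive_logprob / sizes
  flagged <- integer(0)
  for (k in 2L:n_chunks) {
    base <- max(1L, k - window):(k - 1L)
    drop_hit <- per_obs[k] < max(per_obs[base]) - pred_drop
    spike_hit <- rows$annealing_steps[k] >
      stats::median(rows$annealing_steps[base]) + step_spike
    if (drop_hit || spike_hit) flagged <- c(flagged, k)
  }
  flagged
}
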
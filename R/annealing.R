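#' Incremental importance log-weights for a temperature increment
#'
#' Raising the chunk likelihood from power `lambda` to `lambda + delta`
#' multiplies each particle's weight by its chunk likelihood to the power
#' `delta`; in the log domain the increment is simply `delta * loglik`. A
#' `-Inf` chunk log-likelihood (zero-probability record) gives weight zero
#' for any positive `delta`, and `delta = 0` leaves all weights unchanged.
#'
#' @param chunk_logliks Length-`M` vector of chunk log-likelihoods, one per
#'   particle (may contain `-Inf`).
#' @param delta Temperature increment (>= 0).
#' @return Length-`M` vector of incremental log-weights.
#' @export
incremental_log_weights <- function(chunk_logliks, delta) {
  stopifnot(delta >= 0)
  if (delta == 0) return(rep(0, length(chunk_logliks)))
  delta * chunk_logliks
}

#' Effective sample size of a set of log-weights
#'
#' `ESS = (sum w)^2 / sum(w^2)`, computed stably in the log domain; the value
#' lies in `[1, M]`, equal to `M` for equal weights and approaching 1 as a
#' single weight dominates.
#'
#' @param log_weights Numeric vector of (incremental) log-weights; at least
#'   one entry must be finite.
#' @return The effective sample size.
#' @export
ess <- function(log_weights) {
  if (length(log_weights) == 0L || all(log_weights == -Inf)) {
    stop("degenerate ensemble: no particle has positive weight",
         call. = FALSE)
  }
  exp(2 * logsumexp(log_weights) - logsumexp(2 * log_weights))
}

#' Choose the next temperature increment adaptively
#'
#' Selects the increment `delta` of the annealing schedule for the current
#' chunk: if even the full remaining jump to `lambda = 1` keeps the
#' incremental-weight ESS at or above `target_ess`, the schedule finishes in
#' one step (`delta = 1 - lambda`); otherwise `delta` solves
#' `ESS(delta) = target_ess` on `(0, 1 - lambda)`. Since `ESS(0) = M` and
#' ESS need not be monotone in pathological cases, the root is bracketed by
#' scanning 16 subintervals from the left and refined by bisection to an
#' absolute tolerance of `1e-6` in `delta` (floored at `1e-6` so that
#' repeated increments always terminate).
#'
#' @param chunk_logliks Length-`M` vector of per-particle chunk
#'   log-likelihoods.
#' @param lambda Current inverse temperature, `0 <= lambda < 1`.
#' @param target_ess Target ESS in `[1, M]`.
#' @return The increment `delta` in `(0, 1 - lambda]`.
#' @export
find_delta <- function(chunk_logliks, lambda, target_ess) {
  M <- length(chunk_logliks)
  stopifnot(lambda >= 0, lambda < 1)
  if (target_ess > M) {
    stop("target_ess (", target_ess, ") exceeds the number of particles (",
         M, ")", call. = FALSE)
  }
  if (target_ess < 1) target_ess <- 1
  hi <- 1 - lambda
  f <- function(d) ess(incremental_log_weights(chunk_logliks, d)) - target_ess
  if (f(hi) >= 0) return(hi)
  # bracket the smallest root: f(0) = M - target >= 0, f(hi) < 0
  a <- 0
  b <- hi
  grid <- hi * seq_len(16L) / 16L
  for (g in grid) {
    if (f(g) < 0) { b <- g; break }
    a <- g
  }
  while (b - a > 1e-6) {
    mid <- (a + b) / 2
    if (f(mid) >= 0) a <- mid else b <- mid
  }
  max((a + b) / 2, 1e-6)
}

#' Particle ensemble constructor
#'
#' Bundles particle positions, velocities and cumulative importance
#' log-weights.
#'
#' @param theta `dim x M` particle position matrix.
#' @param v `dim x M` velocity matrix (defaults to zero).
#' @param log_weights Length-`M` cumulative log-weights (default 0, i.e.
#'   unit weights: the prior's normalizing constant).
#' @return A list of class `particle_ensemble`.
#' @export
particle_ensemble <- function(theta, v = NULL,
                              log_weights = rep(0, ncol(theta))) {
  if (is.null(v)) v <- matrix(0, nrow(theta), ncol(theta))
  stopifnot(ncol(theta) >= 1L, length(log_weights) == ncol(theta),
            all(dim(v) == dim(theta)))
  structure(list(theta = theta, v = v, log_weights = log_weights,
                 M = ncol(theta)),
            class = "particle_ensemble")
}

#' Apply a temperature increment to the cumulative weights
#'
#' @param ens A [particle_ensemble()].
#' @param chunk_logliks Per-particle chunk log-likelihoods.
#' @param delta Temperature increment in `[0, 1]`.
#' @return The ensemble with `log_weights` incremented by
#'   `delta * chunk_logliks`.
#' @export
update_weights <- function(ens, chunk_logliks, delta) {
  ens$log_weights <- ens$log_weights +
    incremental_log_weights(chunk_logliks, delta)
  ens
}

#' Resample particles proportionally to their weights
#'
#' Draws `M` particle indices proportionally to the normalized weights
#' (systematic resampling by default, multinomial optionally), copies
#' positions and velocities accordingly, and resets every log-weight to the
#' log of the pre-resampling mean weight. The mean weight — and hence the
#' running evidence estimate — is preserved exactly.
#'
#' @param ens A [particle_ensemble()].
#' @param method `"systematic"` or `"multinomial"`.
#' @return The resampled ensemble; the selected indices are attached as
#'   attribute `"indices"`.
#' @export
resample <- function(ens, method = c("systematic", "multinomial")) {
  method <- match.arg(method)
  lw <- ens$log_weights
  lse <- logsumexp(lw)
  if (lse == -Inf) {
    stop("degenerate ensemble: all weights are zero", call. = FALSE)
  }
  w <- exp(lw - lse)
  M <- ens$M
  idx <- if (method == "multinomial") {
    sample.int(M, M, replace = TRUE, prob = w)
  } else {
    u <- (stats::runif(1) + seq_len(M) - 1) / M
    findInterval(u, cumsum(w), rightmost.closed = TRUE) + 1L
  }
  idx <- pmin(idx, M)
  out <- particle_ensemble(ens$theta[, idx, drop = FALSE],
                           ens$v[, idx, drop = FALSE],
                           rep(lse - log(M), M))
  attr(out, "indices") <- idx
  out
}
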
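#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow by shifting by the maximum.
#' Returns `-Inf` for an empty vector or when all entries are `-Inf`.
#'
#' @param x Numeric vector (may contain `-Inf`).
#' @return A single numeric value.
#' @export
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf, or contains +Inf
  m + log(sum(exp(x - m)))
}

#' Numerically stable log of the mean of exponentials
#'
#' @param x Numeric vector of log values.
#' @return `logsumexp(x) - log(length(x))`.
#' @export
logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Coerce a parameter vector or matrix to the dim x M column layout used
# throughout: one particle per column.
as_theta_matrix <- function(theta, dim) {
  if (is.null(dim(theta))) {
    if (length(theta) != dim) {
      stop("parameter vector has length ", length(theta),
           " but the model has ", dim, " parameters", call. = FALSE)
    }
    theta <- matrix(theta, nrow = dim, ncol = 1L)
  } else if (nrow(theta) != dim) {
    stop("parameter matrix has ", nrow(theta),
         " rows but the model has ", dim, " parameters", call. = FALSE)
  }
  theta
}

# Records are stored as a numeric matrix with one observation per row.
as_records <- function(records, width = NULL) {
  if (is.data.frame(records)) records <- as.matrix(records)
  if (is.null(dim(records))) records <- matrix(records, ncol = 1L)
  if (!is.null(width) && ncol(records) != width) {
    stop("records have ", ncol(records), " columns; model expects ", width,
         call. = FALSE)
  }
  records
}

# Sum the per-record log-likelihood matrix (n x M) over records, with the
# empty-data convention that an empty sum is 0 for every particle. A bare
# vector is read as a single particle's per-record terms.
sum_loglik <- function(ll) {
  if (is.null(dim(ll))) ll <- matrix(ll, ncol = 1L)
  if (nrow(ll) == 0L) return(rep(0, ncol(ll)))
  colSums(ll)
}

# Deterministic derived seed for sub-tasks, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629)
}
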
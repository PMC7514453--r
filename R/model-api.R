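#' Construct a model specification
#'
#' A model specification is the contract every sampler in this package works
#' against: an unconstrained parameter space of fixed dimension, a log prior
#' density and its gradient, per-observation log-likelihood terms and the
#' gradient of their sum, and a prior sampler. All parameter arguments use a
#' column-per-particle layout (`dim x M` matrix), so the likelihood and
#' gradient callbacks are evaluated for a whole particle ensemble in one call.
#'
#' Constrained quantities (variances, mixture weights) must be
#' reparameterized by the model onto the unconstrained scale (log-variance,
#' softmax logits): the Hamiltonian dynamics used for sampling operate on
#' unconstrained Euclidean space. A record the model assigns zero probability
#' must yield a `-Inf` log-likelihood term rather than an error; downstream
#' importance-weight arithmetic treats it as weight zero.
#'
#' @param name Short model identifier.
#' @param dim Number of (unconstrained) parameters; must be >= 1.
#' @param record_width Number of columns of a data record.
#' @param log_prior `function(theta)` returning a length-`M` vector of log
#'   prior densities for a `dim x M` parameter matrix.
#' @param grad_log_prior `function(theta)` returning a `dim x M` gradient
#'   matrix.
#' @param loglik_terms `function(theta, records)` returning an `n x M` matrix
#'   of per-record log-likelihoods for an `n x record_width` record matrix.
#' @param grad_loglik_sum `function(theta, records)` returning the `dim x M`
#'   gradient of the summed log-likelihood.
#' @param sample_prior `function(M)` returning a `dim x M` matrix of prior
#'   draws (uses R's global RNG stream).
#' @param simulate Optional `function(theta, N)` drawing `N` i.i.d. records
#'   given a single parameter vector; used by [simulate_dataset()].
#' @param exact_log_evidence Optional `function(records)` returning the exact
#'   log marginal likelihood, when available in closed form.
#' @param extra Optional list of model hyperparameters to carry along.
#' @return An object of class `sgais_model`.
#' @seealso [make_linreg_model()], [make_logreg_model()], [make_gmm_model()]
#' @export
new_model <- function(name, dim, record_width,
                      log_prior, grad_log_prior,
                      loglik_terms, grad_loglik_sum,
                      sample_prior, simulate = NULL,
                      exact_log_evidence = NULL, extra = list()) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) {
    stop("a model must have at least one parameter", call. = FALSE)
  }
  # normalize the parameter argument so model callbacks can rely on the
  # dim x M matrix layout even when handed a bare vector
  wrap <- function(f) {
    if (is.null(f)) return(NULL)
    function(theta, ...) f(as_theta_matrix(theta, dim), ...)
  }
  log_prior <- wrap(log_prior)
  grad_log_prior <- wrap(grad_log_prior)
  loglik_terms <- wrap(loglik_terms)
  grad_loglik_sum <- wrap(grad_loglik_sum)
  structure(
    list(name = name, dim = dim, record_width = as.integer(record_width),
         log_prior = log_prior, grad_log_prior = grad_log_prior,
         loglik_terms = loglik_terms, grad_loglik_sum = grad_loglik_sum,
         sample_prior = sample_prior, simulate = simulate,
         exact_log_evidence = exact_log_evidence, extra = extra),
    class = "sgais_model")
}

#' @export
print.sgais_model <- function(x, ...) {
  cat("<sgais_model> ", x$name, ": ", x$dim, " parameters, records of width ",
      x$record_width,
      if (!is.null(x$exact_log_evidence)) ", exact evidence available" else "",
      "\n", sep = "")
  invisible(x)
}

#' Log joint density of parameters and data
#'
#' Returns `log p(theta) + sum_n log p(y_n | theta)` for each particle. The
#' empty-data case returns the log prior alone (an empty sum of likelihood
#' terms is zero, i.e. the evidence of no data is 1). A `-Inf` likelihood
#' term propagates to a `-Inf` joint.
#'
#' @param model An [sgais_model][new_model] object.
#' @param theta Parameter vector, or `dim x M` matrix of particles.
#' @param records Data records: a numeric matrix with one observation per row
#'   (possibly zero rows).
#' @return Numeric vector of length `M` (length 1 for a single parameter
#'   vector).
#' @export
log_joint <- function(model, theta, records) {
  theta <- as_theta_matrix(theta, model$dim)
  records <- as_records(records, model$record_width)
  lp <- model$log_prior(theta)
  if (nrow(records) == 0L) return(lp)
  lp + sum_loglik(model$loglik_terms(theta, records))
}

#' Check a model's gradients against finite differences
#'
#' Compares `grad_log_prior` and `grad_loglik_sum` with central finite
#' differences of `log_prior` and `loglik_terms` at a set of prior draws.
#' This is the standard sanity check before trusting gradient-based samplers
#' with a hand-written model.
#'
#' @param model An [sgais_model][new_model] object.
#' @param records Records at which to test the likelihood gradient (a small
#'   simulated batch is enough).
#' @param n_probes Number of prior draws to test at.
#' @param step Finite-difference step size.
#' @param tol Maximum tolerated absolute discrepancy per coordinate.
#' @return A list with elements `ok` (logical), `max_abs_diff`, and
#'   `worst_component` (`"prior"` or `"likelihood"`).
#' @export
validate_model <- function(model, records, n_probes = 5L,
                           step = 1e-6, tol = 1e-5) {
  stopifnot(inherits(model, "sgais_model"), n_probes >= 1L)
  records <- as_records(records, model$record_width)
  worst <- 0
  worst_comp <- NA_character_
  probes <- model$sample_prior(n_probes)
  for (j in seq_len(n_probes)) {
    th <- probes[, j, drop = FALSE]
    ga_prior <- model$grad_log_prior(th)
    ga_lik <- model$grad_loglik_sum(th, records)
    for (d in seq_len(model$dim)) {
      hp <- th; hp[d, 1L] <- hp[d, 1L] + step
      hm <- th; hm[d, 1L] <- hm[d, 1L] - step
      fd_prior <- (model$log_prior(hp) - model$log_prior(hm)) / (2 * step)
      fd_lik <- (sum_loglik(model$loglik_terms(hp, records)) -
                   sum_loglik(model$loglik_terms(hm, records))) / (2 * step)
      dp <- abs(fd_prior - ga_prior[d, 1L])
      dl <- abs(fd_lik - ga_lik[d, 1L])
      if (dp > worst) { worst <- dp; worst_comp <- "prior" }
      if (dl > worst) { worst <- dl; worst_comp <- "likelihood" }
    }
  }
  list(ok = worst <= tol, max_abs_diff = worst, worst_component = worst_comp)
}

#' Read and write observation datasets
#'
#' Datasets are numeric matrices with one observation per row and named
#' columns (feature columns, then response/label columns). On disk they are
#' stored either as headered CSV or, when the `arrow` package is available,
#' as a Feather (Arrow IPC) columnar binary file. A sidecar JSON manifest
#' (`<path>.manifest.json`) records generator provenance: seed, true
#' parameters, and phase boundaries where applicable.
#'
#' @param records Numeric matrix of observations.
#' @param path Output (or input) file path; the format is chosen by
#'   extension: `.feather` for Arrow IPC, anything else is CSV.
#' @param manifest Optional list serialized alongside the data.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the records matrix, with the manifest (if present) attached as attribute
#'   `"manifest"`.
#' @export
write_dataset <- function(records, path, manifest = NULL) {
  records <- as_records(records)
  df <- as.data.frame(records)
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required to write Feather files",
           call. = FALSE)
    }
    arrow::write_feather(df, path)
  } else if (requireNamespace("data.table", quietly = TRUE)) {
    data.table::fwrite(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required to read Feather files",
           call. = FALSE)
    }
    df <- as.data.frame(arrow::read_feather(path))
  } else if (requireNamespace("data.table", quietly = TRUE)) {
    df <- as.data.frame(data.table::fread(path))
  } else {
    df <- utils::read.csv(path)
  }
  records <- as.matrix(df)
  mf <- paste0(path, ".manifest.json")
  if (file.exists(mf)) {
    attr(records, "manifest") <- jsonlite::read_json(mf, simplifyVector = TRUE)
  }
  records
}
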
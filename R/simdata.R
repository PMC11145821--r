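# Synthetic-data generator for the simulation study: 8 confounders
# (4 correlated Gaussian + 4 Bernoulli), logistic binary exposure,
# p-dimensional mediators with sparse true effects, continuous outcome.

#' Simulation configuration
#'
#' Builds the parameter set of the simulation study. The defaults are the
#' study conditions of the benchmark: eight confounders acting on exposure,
#' mediators and outcome with coefficients `(0.2, 0.2, 0.3, 0.3, 0.2, 0.2,
#' 0.3, 0.3)`, exposure-to-mediator effects `alpha` with first six entries
#' `(0.4, 0.4, 0.5, 0.5, 0.5, 0.5)`, mediator-to-outcome effects `beta`
#' with first eight entries `(0.4, 0.5, 0.5, 0.6, 0, 0, 0.5, 0.5)`, a direct
#' effect `gamma = 0.5`, and outcome intercept `0.5`. Mediators M1-M4 are
#' therefore the true mediators with indirect effects
#' `(0.16, 0.20, 0.25, 0.30)`; M5-M6 have only the exposure-to-mediator path
#' and M7-M8 only the mediator-to-outcome path.
#'
#' @param n sample size.
#' @param p number of candidate mediators.
#' @param rho mediator-error autocorrelation in `[0, 1)`. With `rho = 0`
#'   mediator errors are i.i.d. normal with variance
#'   `mediator_error_var`; with `rho > 0` error rows are drawn from a
#'   p-variate normal with covariance `rho^|k - k'|` (unit diagonal by
#'   default, see `scale_correlated_errors`).
#' @param alpha,beta optional length-`p` effect vectors; defaults pad the
#'   sparse study-condition vectors with zeros.
#' @param theta,phi,eta length-8 confounder effects on exposure, mediators
#'   (shared across mediators) and outcome.
#' @param gamma direct exposure effect on the outcome.
#' @param intercept_a outcome intercept.
#' @param mediator_error_var variance of the independent mediator errors
#'   (`rho = 0` branch). The study condition `1.2` is read as a variance,
#'   which keeps null-mediator pairwise correlations near 0.3.
#' @param scale_correlated_errors if `TRUE`, the `rho > 0` covariance is
#'   multiplied by `mediator_error_var`; the default `FALSE` keeps the
#'   printed unit-diagonal autocorrelation matrix.
#' @return a `sim_config` list.
#' @examples
#' cfg <- sim_config(n = 300, p = 1000)
#' cfg$alpha[1:6]
#' @export
sim_config <- function(n = 500, p = 1000, rho = 0,
                       alpha = NULL, beta = NULL,
                       theta = c(0.2, 0.2, 0.3, 0.3, 0.2, 0.2, 0.3, 0.3),
                       phi = c(0.2, 0.2, 0.3, 0.3, 0.2, 0.2, 0.3, 0.3),
                       eta = c(0.2, 0.2, 0.3, 0.3, 0.2, 0.2, 0.3, 0.3),
                       gamma = 0.5, intercept_a = 0.5,
                       mediator_error_var = 1.2,
                       scale_correlated_errors = FALSE) {
  assert_scalar_number(n, "n", lower = 2)
  assert_scalar_number(p, "p", lower = 1)
  assert_scalar_number(rho, "rho", lower = 0, upper = 1, closed_upper = FALSE)
  assert_scalar_number(mediator_error_var, "mediator_error_var", lower = 0,
                       closed_lower = FALSE)
  stopifnot(length(theta) == 8, length(phi) == 8, length(eta) == 8)
  pad <- function(v, head) {
    if (!is.null(v)) {
      if (length(v) != p) abort("`alpha`/`beta` must have length p")
      return(v)
    }
    out <- numeric(p)
    k <- seq_len(min(p, length(head)))
    out[k] <- head[k]
    out
  }
  structure(list(
    n = as.integer(n), p = as.integer(p), rho = rho,
    alpha = pad(alpha, c(0.4, 0.4, 0.5, 0.5, 0.5, 0.5)),
    beta = pad(beta, c(0.4, 0.5, 0.5, 0.6, 0, 0, 0.5, 0.5)),
    theta = theta, phi = phi, eta = eta,
    gamma = gamma, intercept_a = intercept_a,
    mediator_error_var = mediator_error_var,
    scale_correlated_errors = scale_correlated_errors
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n = %d, p = %d, rho = %.3g\n", x$n, x$p, x$rho))
  nz <- which(x$alpha * x$beta != 0)
  cat(sprintf("  true mediators (alpha*beta != 0): %s\n",
              paste(nz, collapse = ", ")))
  invisible(x)
}

#' Truth labels of a simulation configuration
#'
#' @param config a [sim_config()].
#' @return a tibble with one row per mediator: `mediator`, `alpha`, `beta`,
#'   `alpha_beta` and `true_mediator` (`alpha*beta != 0`).
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble(
    mediator = paste0("M", seq_len(config$p)),
    index = seq_len(config$p),
    alpha = config$alpha,
    beta = config$beta,
    alpha_beta = config$alpha * config$beta,
    true_mediator = config$alpha * config$beta != 0
  )
}

#' Generate the confounder matrix
#'
#' Columns 1-4 are multivariate normal with zero mean, unit variances and
#' pairwise covariance 0.3; columns 5-8 are independent Bernoulli(0.3).
#'
#' @param n sample size (>= 2).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return an `n x 8` numeric matrix with columns `C1..C8`.
#' @export
sim_confounders <- function(n, seed = NULL) {
  assert_scalar_number(n, "n", lower = 2)
  n <- as.integer(n)
  with_seed_maybe(seed, {
    sigma <- matrix(0.3, 4, 4); diag(sigma) <- 1
    z <- matrix(rnorm(n * 4L), n, 4L)
    cont <- z %*% chol(sigma)
    bin <- matrix(rbinom(n * 4L, 1L, 0.3), n, 4L)
    out <- cbind(cont, bin)
    colnames(out) <- paste0("C", 1:8)
    out
  })
}

#' Generate the binary exposure from a logistic model
#'
#' `X_i ~ Bernoulli(1 / (1 + exp(-theta' C_i)))`, with no intercept.
#'
#' @param C confounder matrix with `length(theta)` columns.
#' @param theta confounder-to-exposure coefficients.
#' @inheritParams sim_confounders
#' @return an integer 0/1 vector of length `nrow(C)`.
#' @export
sim_exposure <- function(C, theta = c(0.2, 0.2, 0.3, 0.3, 0.2, 0.2, 0.3, 0.3),
                         seed = NULL) {
  C <- as.matrix(C)
  if (ncol(C) != length(theta)) {
    abort(sprintf("`C` has %d columns but `theta` has length %d",
                  ncol(C), length(theta)))
  }
  pr <- plogis(drop(C %*% theta))
  with_seed_maybe(seed, rbinom(nrow(C), 1L, pr))
}

# AR(1) error matrix with unit marginal variance: e[,1] ~ N(0,1),
# e[,k] = rho e[,k-1] + sqrt(1-rho^2) z. Gives corr(e_k, e_k') = rho^|k-k'|.
ar1_errors <- function(n, p, rho) {
  z <- matrix(rnorm(n * p), n, p)
  if (rho == 0 || p == 1L) return(z)
  e <- z
  w <- sqrt(1 - rho^2)
  for (k in 2:p) e[, k] <- rho * e[, k - 1L] + w * z[, k]
  e
}

#' Generate the mediator matrix
#'
#' `M_ik = a_k + alpha_k X_i + phi' C_i + e_ik` with per-mediator intercepts
#' `a_k ~ U(0, 1)` drawn once per mediator. With `rho = 0` the errors are
#' i.i.d. `N(0, mediator_error_var)`; with `rho > 0` error rows follow a
#' p-variate normal with autocorrelation `rho^|k-k'|` (unit diagonal unless
#' `scale_correlated_errors`).
#'
#' @param X binary exposure vector.
#' @param C confounder matrix.
#' @param config a [sim_config()]; `config$p`, `config$alpha`, `config$phi`,
#'   `config$rho` and the error-scale settings are used.
#' @inheritParams sim_confounders
#' @return an `n x p` matrix with columns `M1..Mp`.
#' @export
sim_mediators <- function(X, C, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  C <- as.matrix(C)
  n <- length(X); p <- config$p
  if (nrow(C) != n) abort("`X` and `C` have inconsistent sizes")
  if (ncol(C) != length(config$phi)) abort("`C` incompatible with `config$phi`")
  with_seed_maybe(seed, {
    a_k <- runif(p)
    e <- ar1_errors(n, p, config$rho)
    scale_sd <- if (config$rho == 0 || config$scale_correlated_errors) {
      sqrt(config$mediator_error_var)
    } else 1
    conf <- drop(C %*% config$phi)
    M <- tcrossprod(X, config$alpha) + conf + e * scale_sd
    M <- sweep(M, 2L, a_k, `+`)
    colnames(M) <- paste0("M", seq_len(p))
    M
  })
}

#' Generate the continuous outcome
#'
#' `Y_i = a + gamma X_i + beta' M_i + eta' C_i + eps_i`, `eps ~ N(0, 1)`.
#'
#' @param X binary exposure vector.
#' @param M mediator matrix.
#' @param C confounder matrix.
#' @param config a [sim_config()].
#' @inheritParams sim_confounders
#' @return a numeric vector of length `n`.
#' @export
sim_outcome <- function(X, M, C, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  M <- as.matrix(M); C <- as.matrix(C)
  n <- length(X)
  if (nrow(M) != n || nrow(C) != n) abort("inconsistent dimensions")
  if (ncol(M) != length(config$beta)) abort("`M` incompatible with `config$beta`")
  mu <- config$intercept_a + config$gamma * X +
    drop(M %*% config$beta) + drop(C %*% config$eta)
  with_seed_maybe(seed, mu + rnorm(n))
}

#' Simulate a full mediation dataset
#'
#' Draws confounders, exposure, mediators and outcome in one call. RNG
#' streams are split per component from the master seed, so e.g. changing
#' `p` does not perturb the exposure draw.
#'
#' @param config a [sim_config()].
#' @param seed master seed for the replication.
#' @return a [mediation_dataset()] carrying the truth labels of the
#'   configuration.
#' @examples
#' dat <- sim_dataset(sim_config(n = 100, p = 50), seed = 1)
#' dat
#' @export
sim_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(seed, 4L)
  C <- sim_confounders(config$n, seed = seeds[1])
  X <- sim_exposure(C, config$theta, seed = seeds[2])
  M <- sim_mediators(X, C, config, seed = seeds[3])
  Y <- sim_outcome(X, M, C, config, seed = seeds[4])
  mediation_dataset(X = X, Y = Y, M = M, C = C, truth = sim_truth(config),
                    validate_exposure = FALSE)
}
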
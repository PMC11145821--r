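# Propensity-score estimation and the RA / PSR / IPW / OW adjustment
# machinery shared by screening, penalized estimation and mediation tests.

PS_EPS <- 1e-6  # symmetric clipping bound applied before weight construction

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of the binary exposure on the
#' confounders, with intercept. Fitted probabilities are clipped away from
#' 0 and 1 by `1e-6` before any weight construction.
#'
#' @param C confounder matrix or data frame (no missing values).
#' @param X binary 0/1 exposure with both groups present.
#' @return an object of class `propensity_fit` with elements `scores`
#'   (clipped fitted probabilities), `coefficients`, `converged` and
#'   `n_iterations`. Perfect separation or non-convergence is reported via
#'   a warning and `converged = FALSE`.
#' @examples
#' C <- sim_confounders(200, seed = 1)
#' X <- sim_exposure(C, seed = 2)
#' fit <- fit_propensity(C, X)
#' range(fit$scores)
#' @export
fit_propensity <- function(C, X) {
  C <- as.matrix(C)
  if (anyNA(C)) abort("`C` must not contain missing values")
  assert_binary(X, "X", require_both = TRUE)
  if (nrow(C) != length(X)) abort("`C` and `X` have inconsistent sizes")
  df <- as.data.frame(C)
  fit <- withCallingHandlers(
    glm(X ~ ., family = binomial(), data = cbind(X = X, df)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  raw <- as.numeric(fitted(fit))
  separated <- any(raw < PS_EPS) || any(raw > 1 - PS_EPS)
  converged <- isTRUE(fit$converged) && !separated
  if (!converged) {
    warn("propensity model did not converge cleanly (possible separation); scores clipped")
  }
  structure(list(
    scores = pmin(pmax(raw, PS_EPS), 1 - PS_EPS),
    coefficients = coef(fit),
    converged = converged,
    n_iterations = fit$iter
  ), class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("<propensity_fit> n = %d, converged = %s\n",
              length(x$scores), x$converged))
  cat("  score quantiles:\n")
  print(round(quantile(x$scores, c(0, .25, .5, .75, 1)), 4))
  invisible(x)
}

#' @export
tidy.propensity_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.propensity_fit <- function(x, ...) {
  tibble(n = length(x$scores), converged = x$converged,
         n_iterations = x$n_iterations,
         ps_min = min(x$scores), ps_max = max(x$scores))
}

#' Construct per-sample adjustment weights
#'
#' `ipw`: `w_i = X_i / pi_i + (1 - X_i) / (1 - pi_i)` (all >= 1, unbounded
#' as the score approaches 0 or 1). `ow`: `w_i = 1 - pi_i` for exposed,
#' `pi_i` for unexposed (bounded in (0, 1), largest near `pi = 0.5`).
#'
#' @param fit a [fit_propensity()] result (or any object with a `scores`
#'   element).
#' @param X binary exposure aligned with `fit$scores`.
#' @param scheme `"ipw"` or `"ow"`.
#' @return an object of class `weight_vector`: the numeric weights with
#'   attributes `scheme` and `scores`.
#' @export
compute_weights <- function(fit, X, scheme = c("ow", "ipw")) {
  scheme <- match.arg(scheme)
  pi <- if (is.list(fit)) fit$scores else as.numeric(fit)
  if (length(pi) != length(X)) abort("`fit` scores and `X` have different lengths")
  assert_binary(X, "X", require_both = FALSE)
  pi <- pmin(pmax(pi, PS_EPS), 1 - PS_EPS)
  w <- switch(scheme,
    ipw = X / pi + (1 - X) / (1 - pi),
    ow  = ifelse(X == 1, 1 - pi, pi))
  structure(w, scheme = scheme, scores = pi, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  d <- weight_diagnostics(x)
  cat(sprintf("<weight_vector> scheme = %s, n = %d\n", attr(x, "scheme"),
              length(x)))
  cat(sprintf("  range [%.4g, %.4g], ESS = %.1f (%.0f%% of n)\n",
              d$min_weight, d$max_weight, d$ess, 100 * d$ess / d$n))
  invisible(x)
}

#' Weight diagnostics
#'
#' Reports the weight range and the effective sample size
#' `(sum w)^2 / sum(w^2)` — the usual check that a weighting scheme has not
#' concentrated the analysis on a handful of samples.
#'
#' @param w a [compute_weights()] result or plain positive weights.
#' @return a one-row tibble with `scheme`, `n`, `min_weight`, `max_weight`,
#'   `ess`.
#' @export
weight_diagnostics <- function(w) {
  scheme <- attr(w, "scheme") %||% "custom"
  w <- as.numeric(w)
  tibble(scheme = scheme, n = length(w),
         min_weight = min(w), max_weight = max(w),
         ess = sum(w)^2 / sum(w^2))
}

#' Weighted least squares with robust or naive standard errors
#'
#' The shared fitting engine behind every weighted stage. Point estimates
#' solve the weighted normal equations; standard errors default to
#' heteroskedasticity-robust (HC0 sandwich, appropriate because the
#' adjustment weights are not precision weights), with classical WLS errors
#' as an option. P-values are two-sided normal.
#'
#' @param response numeric response vector.
#' @param design numeric design matrix (include the intercept column
#'   yourself, or use `add_intercept = TRUE`).
#' @param weights positive weights; `NULL` for ordinary least squares.
#' @param se `"robust"` (default) or `"naive"`.
#' @param add_intercept prepend a column of ones (default `TRUE`).
#' @return a tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
weighted_linear_fit <- function(response, design, weights = NULL,
                                se = c("robust", "naive"),
                                add_intercept = TRUE) {
  se <- match.arg(se)
  design <- as.matrix(design)
  if (add_intercept) {
    design <- cbind(`(Intercept)` = 1, design)
  }
  n <- length(response)
  if (nrow(design) != n) abort("`response` and `design` have inconsistent sizes")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w <= 0) || anyNA(w)) abort("`weights` must be positive and non-missing")
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))

  xtw <- t(design * w)
  xtwx <- xtw %*% design
  qrx <- qr(xtwx)
  if (qrx$rank < ncol(design)) {
    bad <- colnames(design)[qrx$pivot[(qrx$rank + 1):ncol(design)]]
    abort(paste0("design is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  bread <- solve(qrx, diag(ncol(design)))
  beta <- drop(bread %*% (xtw %*% response))
  resid <- response - drop(design %*% beta)
  if (se == "robust") {
    meat <- crossprod(design * (w * resid))
    vc <- bread %*% meat %*% bread
  } else {
    df <- max(n - ncol(design), 1)
    sigma2 <- sum(w * resid^2) / df
    vc <- sigma2 * bread
  }
  se_vec <- sqrt(pmax(diag(vc), 0))
  z <- ifelse(se_vec > 0, beta / se_vec, ifelse(beta == 0, 0, Inf * sign(beta)))
  tibble(term = colnames(design), estimate = unname(beta),
         std_error = unname(se_vec), statistic = unname(z),
         p_value = unname(2 * pnorm(-abs(z))))
}
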
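# Mediation-level inference: per-candidate exposure->mediator tests under
# the chosen adjustment, joint-significance (max-P) testing with BH
# adjustment under the uniform null, and the 3-component composite-null
# mixture FDR estimator.

#' Exposure-to-mediator inference for a candidate set
#'
#' Estimates `alpha_k` for every candidate mediator under the chosen
#' adjustment: ordinary regression of `M_k` on exposure and confounders
#' (`ra`), on exposure and the propensity score (`psr`), or the weighted
#' regression of `M_k` on exposure and confounders with the scheme's
#' weights and robust standard errors (`ipw`, `ow`).
#'
#' @param dataset a [mediation_dataset()].
#' @param candidate_set integer indices (or mediator ids) of the
#'   candidates; an empty set returns an empty tibble.
#' @param adjustment `"ra"`, `"psr"`, `"ipw"` or `"ow"`.
#' @param ps_fit optional pre-computed [fit_propensity()].
#' @param se `"robust"` (default) or `"naive"` for the weighted schemes.
#' @return a tibble with `mediator`, `index`, `alpha_hat`, `alpha_se`,
#'   `p_alpha`.
#' @export
alpha_inference <- function(dataset, candidate_set,
                            adjustment = c("ow", "ipw", "psr", "ra"),
                            ps_fit = NULL, se = "robust") {
  adjustment <- match.arg(adjustment)
  stopifnot(inherits(dataset, "mediation_dataset"))
  if (is.character(candidate_set)) {
    candidate_set <- match(candidate_set, dataset$mediator_ids)
  }
  candidate_set <- as.integer(candidate_set)
  if (length(candidate_set) == 0) {
    return(tibble(mediator = character(), index = integer(),
                  alpha_hat = numeric(), alpha_se = numeric(),
                  p_alpha = numeric()))
  }
  assert_binary(dataset$X, "X", require_both = TRUE)
  sub <- dataset
  sub$M <- dataset$M[, candidate_set, drop = FALSE]
  weights <- NULL
  if (adjustment %in% c("psr", "ipw", "ow") && is.null(ps_fit)) {
    ps_fit <- fit_propensity(dataset$C, dataset$X)
  }
  if (adjustment %in% c("ipw", "ow")) {
    weights <- compute_weights(ps_fit, dataset$X, scheme = adjustment)
  }
  res <- alpha_all(sub, adjustment, ps_fit = ps_fit, weights = weights, se = se)
  tibble(mediator = dataset$mediator_ids[candidate_set],
         index = candidate_set,
         alpha_hat = res$estimate, alpha_se = res$std_error,
         p_alpha = res$p_value)
}

#' Joint-significance test under the uniform null with BH adjustment
#'
#' The raw mediation p-value of candidate `k` is
#' `P_raw,k = max(P_alpha,k, P_beta,k)`; Benjamini-Hochberg adjustment
#' `min(P_raw,k * q / r_k, 1)` (with the step-up monotonicity enforcement)
#' controls the FDR across the `q` candidates under the uniform-null
#' reading of the max-P statistic.
#'
#' @param p_alpha,p_beta equal-length p-value vectors in `[0, 1]`.
#' @param level significance level for the calls (default 0.05).
#' @param family_size number of tests the BH correction accounts for;
#'   defaults to the number of candidates supplied. A workflow that tests
#'   only the penalization-selected subset of the `d` screened candidates
#'   passes `d` here, treating the unselected screened candidates as
#'   never-significant tests.
#' @return a tibble with `p_raw`, `p_adjusted`, `significant`.
#' @examples
#' js_uniform(c(0.001, 0.2), c(0.01, 0.01))
#' @export
js_uniform <- function(p_alpha, p_beta, level = 0.05, family_size = NULL) {
  check_pvalues(p_alpha, "p_alpha")
  check_pvalues(p_beta, "p_beta")
  if (length(p_alpha) != length(p_beta)) abort("p-value vectors differ in length")
  family_size <- family_size %||% length(p_alpha)
  if (family_size < length(p_alpha)) abort("`family_size` below the number of candidates")
  p_raw <- pmax(p_alpha, p_beta)
  p_adj <- p.adjust(p_raw, method = "BH", n = family_size)
  tibble(p_raw = p_raw, p_adjusted = p_adj, significant = p_adj <= level)
}

check_pvalues <- function(p, name) {
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1))) {
    abort(sprintf("`%s` must lie in [0, 1] without missing values", name))
  }
}

#' Estimate the composite-null component proportions
#'
#' The mediation null splits into three components: both effects null
#' (`pi00`), only the exposure->mediator effect null (`pi01`), only the
#' mediator->outcome effect null (`pi10`). Marginal null fractions of each
#' p-value set are estimated by Storey's method at `lambda` and combined
#' under cross-independence:
#' `pi00 = pi_a0 pi_b0`, `pi01 = pi_a0 (1 - pi_b0)`,
#' `pi10 = (1 - pi_a0) pi_b0`.
#'
#' @param p_alpha,p_beta p-value vectors over `q >= 2` candidates.
#' @param lambda Storey tuning point (default 0.5).
#' @return named numeric vector `c(pi00, pi01, pi10)`; the three sum to
#'   at most 1.
#' @export
estimate_null_proportions <- function(p_alpha, p_beta, lambda = 0.5) {
  check_pvalues(p_alpha, "p_alpha"); check_pvalues(p_beta, "p_beta")
  if (length(p_alpha) != length(p_beta)) abort("p-value vectors differ in length")
  if (length(p_alpha) < 2) abort("need at least 2 candidates to estimate null proportions")
  assert_scalar_number(lambda, "lambda", lower = 0, upper = 1,
                       closed_lower = FALSE, closed_upper = FALSE)
  storey <- function(p) {
    min(1, mean(p > lambda) / (1 - lambda))
  }
  pa0 <- storey(p_alpha); pb0 <- storey(p_beta)
  c(pi00 = pa0 * pb0, pi01 = pa0 * (1 - pb0), pi10 = (1 - pa0) * pb0)
}

#' Composite-null mixture FDR for the max-P statistic
#'
#' For a threshold `t`, the expected false positives from the three null
#' components are `V00 = q pi00 t^2` (both p-values must fall below `t`),
#' `V01 = q pi01 t` and `V10 = q pi10 t` (the non-null p-value is treated
#' as stochastically no larger than uniform). The estimated pointwise FDR
#' at each candidate's own `P_raw` is
#' `(V00 + V01 + V10) / max(R(t), 1)` with `R(t)` the observed count of
#' `P_raw <= t`, clipped to `[0, 1]`, followed by a step-up monotonicity
#' correction so calls are threshold-consistent.
#'
#' @param p_alpha,p_beta p-value vectors.
#' @param proportions output of [estimate_null_proportions()]; estimated
#'   from the inputs when `NULL`.
#' @param level significance level for the calls (default 0.05).
#' @return a tibble with `p_raw`, `fdr`, `significant`.
#' @export
js_mixture_fdr <- function(p_alpha, p_beta, proportions = NULL,
                           level = 0.05) {
  check_pvalues(p_alpha, "p_alpha"); check_pvalues(p_beta, "p_beta")
  if (length(p_alpha) != length(p_beta)) abort("p-value vectors differ in length")
  q <- length(p_alpha)
  if (q == 0) {
    return(tibble(p_raw = numeric(), fdr = numeric(),
                  significant = logical()))
  }
  if (is.null(proportions)) {
    proportions <- estimate_null_proportions(p_alpha, p_beta)
  }
  if (any(proportions < 0) || sum(proportions) > 1 + 1e-8) {
    abort("`proportions` must be nonnegative and sum to at most 1")
  }
  p_raw <- pmax(p_alpha, p_beta)
  fdr_at <- function(t) {
    v <- q * (proportions[["pi00"]] * t^2 +
                (proportions[["pi01"]] + proportions[["pi10"]]) * t)
    r <- sum(p_raw <= t)
    min(v / max(r, 1), 1)
  }
  fdr <- vapply(p_raw, fdr_at, numeric(1))
  # step-up monotonicity: the reported FDR at a smaller p_raw never
  # exceeds the FDR at a larger one
  ord <- order(p_raw, decreasing = TRUE)
  fdr[ord] <- cummin(fdr[ord])
  tibble(p_raw = p_raw, fdr = fdr, significant = fdr <= level)
}
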
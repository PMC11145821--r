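# End-to-end workflows. The `hima` path is screening -> MCP selection ->
# joint-significance testing with BH under the uniform null; the `mhima2`
# path is screening -> de-biased Lasso inference -> joint-significance
# testing under the 3-component mixture null.

#' Run a confounder-adjusted high-dimensional mediation analysis
#'
#' Orchestrates propensity-score fitting (when the adjustment needs it),
#' sure-independence screening, the penalized stage and the mediation
#' test.
#'
#' * `test_method = "hima"`: MCP selection on the screened candidates,
#'   ordinary refit of the selected model for mediator p-values, max-P
#'   joint significance with BH adjustment.
#' * `test_method = "mhima2"`: de-biased Lasso estimates and p-values on
#'   all screened candidates, composite-null mixture FDR.
#'
#' @param dataset a [mediation_dataset()].
#' @param test_method `"mhima2"` (default) or `"hima"`.
#' @param adjustment confounding adjustment: `"ow"`, `"ipw"`, `"psr"` or
#'   `"ra"`.
#' @param level significance level for mediation calls (default 0.05).
#' @param d screening dimension override (default [sis_dimension()] of n).
#' @param basis screening basis, `"beta"` or `"alpha_beta"`.
#' @param seed seed for the cross-validation folds of the penalized stage;
#'   the whole run is deterministic given the dataset and this seed.
#' @param weighted_penalized fit the penalized outcome model with the
#'   scheme's weights (default `TRUE`, the scheme-consistent reading: the
#'   confounders stay in the model and the weights carry the adjustment
#'   into the outcome stage); `FALSE` gives the unweighted variant of the
#'   same model. Ignored for `ra`/`psr`, which have no weights.
#' @param alpha_se `"robust"` (default) or `"naive"` standard errors for
#'   the weighted exposure->mediator fits.
#' @return an object of class `hdma_result`: `report` (per-candidate
#'   tibble with `alpha_hat`, `beta_hat`, `alpha_beta`, `p_alpha`,
#'   `p_beta`, `p_raw`, `p_adjusted`, `significant`, `percent_te`),
#'   `gamma_hat` (direct effect), `screen`, `penalized`, `ps_fit` and the
#'   call settings. `tidy()` returns the report, `glance()` a one-row
#'   summary.
#' @examples
#' dat <- sim_dataset(sim_config(n = 150, p = 100), seed = 7)
#' fit <- hdma(dat, test_method = "mhima2", adjustment = "ow", seed = 7)
#' dplyr::filter(tidy(fit), significant)
#' @export
hdma <- function(dataset,
                 test_method = c("mhima2", "hima"),
                 adjustment = c("ow", "ipw", "psr", "ra"),
                 level = 0.05, d = NULL, basis = "beta", seed = 1L,
                 weighted_penalized = TRUE, alpha_se = "robust") {
  test_method <- match.arg(test_method)
  adjustment <- match.arg(adjustment)
  stopifnot(inherits(dataset, "mediation_dataset"))

  scr <- screen_mediators(dataset, adjustment = adjustment, basis = basis,
                          d = d)
  kept <- scr$kept
  Mk <- dataset$M[, kept, drop = FALSE]
  covs <- switch(adjustment,
    psr = matrix(scr$ps_fit$scores, ncol = 1,
                 dimnames = list(NULL, "PS")),
    dataset$C)
  pen_weights <- if (weighted_penalized && !is.null(scr$weights)) {
    as.numeric(scr$weights)
  } else NULL

  if (test_method == "mhima2") {
    deb <- fit_debiased_lasso(dataset$Y, dataset$X, Mk, covs,
                              weights = pen_weights, seed = seed)
    beta_tab <- tibble(index = kept,
                       beta_hat = deb$table$estimate,
                       beta_se = deb$table$std_error,
                       p_beta = deb$table$p_value)
    gamma_hat <- deb$gamma_hat
    candidates <- kept
    penalized <- deb
  } else {
    mcp <- fit_mcp(dataset$Y, dataset$X, Mk, covs, weights = pen_weights)
    sel <- mcp$selected
    candidates <- kept[sel]
    penalized <- mcp
    if (length(sel)) {
      # robust SEs whenever adjustment weights enter the fit: they are
      # not precision weights, so the classical WLS variance is invalid
      refit <- weighted_linear_fit(
        dataset$Y,
        cbind(X = dataset$X, Mk[, sel, drop = FALSE], covs),
        weights = pen_weights,
        se = if (is.null(pen_weights)) "naive" else "robust")
      med_terms <- seq_along(sel) + 2L  # after intercept and X
      beta_tab <- tibble(index = candidates,
                         beta_hat = refit$estimate[med_terms],
                         beta_se = refit$std_error[med_terms],
                         p_beta = refit$p_value[med_terms])
      gamma_hat <- refit$estimate[refit$term == "X"]
    } else {
      beta_tab <- tibble(index = integer(), beta_hat = numeric(),
                         beta_se = numeric(), p_beta = numeric())
      gamma_hat <- NA_real_
    }
  }

  al <- alpha_inference(dataset, candidates, adjustment = adjustment,
                        ps_fit = scr$ps_fit, se = alpha_se)
  report <- dplyr::left_join(al, beta_tab, by = "index")
  if (nrow(report)) {
    if (test_method == "mhima2") {
      mt <- js_mixture_fdr(report$p_alpha, report$p_beta, level = level)
      report$p_raw <- mt$p_raw
      report$p_adjusted <- mt$fdr
      report$significant <- mt$significant
    } else {
      # the multiplicity family is the d screened candidates: unselected
      # screened mediators count as tests that were never significant
      mt <- js_uniform(report$p_alpha, report$p_beta, level = level,
                       family_size = scr$d)
      report$p_raw <- mt$p_raw
      report$p_adjusted <- mt$p_adjusted
      report$significant <- mt$significant
    }
    report$alpha_beta <- report$alpha_hat * report$beta_hat
    total <- gamma_hat + sum(report$alpha_beta[report$significant])
    report$percent_te <- ifelse(report$significant,
                                100 * report$alpha_beta / total, NA_real_)
    report <- report[order(report$p_adjusted, report$p_raw, report$index), ]
  } else {
    report$p_raw <- report$p_adjusted <- numeric(0)
    report$significant <- logical(0)
    report$alpha_beta <- report$percent_te <- numeric(0)
    message("no candidate mediators survived the penalized stage; empty report")
  }

  structure(list(
    report = as_tibble(report),
    gamma_hat = gamma_hat,
    screen = scr, penalized = penalized, ps_fit = scr$ps_fit,
    test_method = test_method, adjustment = adjustment,
    level = level, seed = seed,
    n = length(dataset$X), p = ncol(dataset$M), d = scr$d
  ), class = "hdma_result")
}

#' @export
print.hdma_result <- function(x, ...) {
  cat(sprintf("<hdma_result> %s + %s: n = %d, p = %d, d = %d\n",
              x$test_method, x$adjustment, x$n, x$p, x$d))
  cat(sprintf("  significant mediators at %.2g: %d\n", x$level,
              sum(x$report$significant)))
  if (any(x$report$significant)) {
    print(head(x$report[x$report$significant,
                        c("mediator", "alpha_hat", "beta_hat",
                          "alpha_beta", "percent_te", "p_adjusted")], 10))
  }
  invisible(x)
}

#' @export
tidy.hdma_result <- function(x, ...) x$report

#' @export
glance.hdma_result <- function(x, ...) {
  tibble(test_method = x$test_method, adjustment = x$adjustment,
         n = x$n, p = x$p, d = x$d,
         n_candidates = nrow(x$report),
         n_significant = sum(x$report$significant),
         gamma_hat = x$gamma_hat, level = x$level)
}
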
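# Replication benchmark: per-mediator TPR, overall TPR, FDP, and
# Mean/MSE of the estimated mediation effects over simulated replications.

#' Summarise replications into selection and estimation metrics
#'
#' Given per-replication candidate reports and the truth labels, computes
#' for each true mediator the true positive rate (fraction of replications
#' in which it is called significant), the overall TPR (their arithmetic
#' mean), the false discovery proportion (per-replication
#' `#false positives / max(#significant, 1)`, averaged; 0/0 counts as 0),
#' and the Monte-Carlo mean and mean squared error of the estimated
#' mediation effect `alpha_hat * beta_hat` per true mediator. `mean_est` /
#' `mse` average over every replication in which the mediator carries an
#' estimate (i.e. survived screening into the tested candidate set);
#' `mean_est_selected` / `mse_selected` condition on the mediator being
#' called significant.
#'
#' @param reports list of per-replication report tibbles (from
#'   `tidy(hdma(...))`) with columns `index`, `alpha_beta`, `significant`.
#' @param truth truth tibble (see [sim_truth()]).
#' @return a list of class `sim_metrics`: `per_mediator` tibble (`index`,
#'   `alpha_beta_true`, `tpr`, `mean_est`, `mse`, `mean_est_selected`,
#'   `mse_selected`, `n_selected`), `overall_tpr`, `fdp`, `reps`, and the
#'   Monte-Carlo standard errors `overall_tpr_se` and `fdp_se`.
#' @export
evaluate_replications <- function(reports, truth) {
  if (length(reports) == 0) abort("`reports` must contain at least one replication")
  reports <- lapply(reports, function(r) {
    if (inherits(r, "hdma_result")) r$report else r
  })
  true_idx <- truth$index[truth$true_mediator]
  reps <- length(reports)

  if (length(true_idx) == 0) {
    # all-null truth: only false-discovery behaviour is defined
    fdp_rep <- vapply(reports, function(r) {
      sig <- r$index[r$significant]
      if (length(sig)) 1 else 0
    }, numeric(1))
    return(structure(list(
      per_mediator = tibble(index = integer(), alpha_beta_true = numeric(),
                            tpr = numeric(), n_selected = numeric(),
                            mean_est = numeric(), mse = numeric(),
                            mean_est_selected = numeric(),
                            mse_selected = numeric()),
      overall_tpr = NA_real_, overall_tpr_se = NA_real_,
      fdp = mean(fdp_rep), fdp_se = stats::sd(fdp_rep) / sqrt(reps),
      reps = reps
    ), class = "sim_metrics"))
  }

  hit <- matrix(FALSE, reps, length(true_idx),
                dimnames = list(NULL, paste0("M", true_idx)))
  est_sig <- matrix(NA_real_, reps, length(true_idx))
  est_all <- matrix(NA_real_, reps, length(true_idx))
  fdp_rep <- numeric(reps)
  for (r in seq_len(reps)) {
    rep_tab <- reports[[r]]
    sig_idx <- rep_tab$index[rep_tab$significant]
    hit[r, ] <- true_idx %in% sig_idx
    fp <- length(setdiff(sig_idx, true_idx))
    fdp_rep[r] <- if (length(sig_idx)) fp / length(sig_idx) else 0
    m <- match(true_idx, rep_tab$index)
    est_all[r, ] <- rep_tab$alpha_beta[m]
    est_sig[r, ] <- ifelse(hit[r, ], rep_tab$alpha_beta[m], NA_real_)
  }
  tpr <- colMeans(hit)
  per_mediator <- tibble(
    index = true_idx,
    alpha_beta_true = truth$alpha_beta[match(true_idx, truth$index)],
    tpr = as.numeric(tpr),
    n_selected = colSums(!is.na(est_sig)),
    mean_est = colMeans(est_all, na.rm = TRUE),
    mse = colMeans((est_all - rep(truth$alpha_beta[match(true_idx, truth$index)],
                                  each = reps))^2, na.rm = TRUE),
    mean_est_selected = colMeans(est_sig, na.rm = TRUE),
    mse_selected = colMeans((est_sig - rep(truth$alpha_beta[match(true_idx, truth$index)],
                                           each = reps))^2, na.rm = TRUE)
  )
  overall <- mean(tpr)
  structure(list(
    per_mediator = per_mediator,
    overall_tpr = overall,
    overall_tpr_se = stats::sd(rowMeans(hit)) / sqrt(reps),
    fdp = mean(fdp_rep),
    fdp_se = stats::sd(fdp_rep) / sqrt(reps),
    reps = reps
  ), class = "sim_metrics")
}

#' @export
print.sim_metrics <- function(x, ...) {
  cat(sprintf("<sim_metrics> %d replications: overall TPR = %.4f (SE %.4f), FDP = %.4f\n",
              x$reps, x$overall_tpr, x$overall_tpr_se, x$fdp))
  print(x$per_mediator)
  invisible(x)
}

#' @export
tidy.sim_metrics <- function(x, ...) x$per_mediator

#' @export
glance.sim_metrics <- function(x, ...) {
  tibble(reps = x$reps, overall_tpr = x$overall_tpr,
         overall_tpr_se = x$overall_tpr_se, fdp = x$fdp, fdp_se = x$fdp_se)
}

#' Run one benchmark cell
#'
#' Simulates `reps` independent replications of a scenario, runs the
#' workflow on each, and summarises them with [evaluate_replications()].
#' Per-replication seeds are derived from the master seed by a
#' counter-based split, so any cell and any replication can be regenerated
#' independently and the metrics do not depend on execution order.
#'
#' @param config a [sim_config()] describing the scenario.
#' @param test_method,adjustment workflow settings (see [hdma()]).
#' @param reps number of replications.
#' @param seed master seed.
#' @param stream integer offset separating cells run from one master seed.
#' @param keep_reports keep the per-replication reports (default `FALSE`).
#' @return a `sim_metrics` object (with `reports` attached when requested).
#' @export
run_cell <- function(config, test_method = "mhima2", adjustment = "ow",
                     reps = 100, seed = 1L, stream = 0L,
                     keep_reports = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (reps < 1) abort("`reps` must be at least 1")
  rep_seeds <- split_seed(seed, reps, stream = stream)
  truth <- sim_truth(config)
  reports <- purrr::map(seq_len(reps), function(r) {
    dat <- sim_dataset(config, seed = rep_seeds[r])
    fit <- hdma(dat, test_method = test_method, adjustment = adjustment,
                seed = rep_seeds[r])
    fit$report
  })
  metrics <- evaluate_replications(reports, truth)
  metrics$test_method <- test_method
  metrics$adjustment <- adjustment
  metrics$config <- config
  if (keep_reports) metrics$reports <- reports
  metrics
}

#' Run the simulation benchmark grid
#'
#' Runs every combination of scenario and method cell and emits two tidy
#' tables: selection metrics (per-mediator and overall TPR, FDP) and
#' estimation metrics (Mean/MSE of the mediation-effect estimates).
#'
#' @param scenarios tibble with columns `n`, `p`, `rho` (one row per
#'   scenario); extra columns are passed to [sim_config()].
#' @param methods tibble with columns `test_method`, `adjustment`.
#' @param reps replications per cell.
#' @param seed master seed; each cell uses an independent stream.
#' @return a list of class `benchmark_result` with tibbles `selection`
#'   (cell x mediator TPR rows plus overall TPR/FDP) and `estimation`
#'   (cell x mediator Mean/MSE rows), and `cells`, the raw `sim_metrics`.
#' @export
run_benchmark <- function(scenarios = tibble(n = c(300, 500), p = 1000, rho = 0),
                          methods = tibble(test_method = c("mhima2", "hima"),
                                           adjustment = "ow"),
                          reps = 100, seed = 1L) {
  grid <- tidyr::crossing(scenario = seq_len(nrow(scenarios)),
                          method = seq_len(nrow(methods)))
  cells <- purrr::pmap(grid, function(scenario, method) {
    sc <- scenarios[scenario, ]
    cfg_args <- as.list(sc[setdiff(names(sc), character(0))])
    cfg <- do.call(sim_config, cfg_args)
    if (sis_dimension(cfg$n) >= cfg$n) {
      warn(sprintf("cell n = %d infeasible (d >= n); skipped", cfg$n))
      return(NULL)
    }
    m <- run_cell(cfg, test_method = methods$test_method[method],
                  adjustment = methods$adjustment[method],
                  reps = reps, seed = seed,
                  stream = scenario * 100L + method)
    m
  })
  keep <- !vapply(cells, is.null, logical(1))
  cells <- cells[keep]
  selection <- purrr::map_dfr(cells, function(m) {
    dplyr::mutate(
      dplyr::select(m$per_mediator, "index", "alpha_beta_true", "tpr"),
      n = m$config$n, p = m$config$p, rho = m$config$rho,
      test_method = m$test_method, adjustment = m$adjustment,
      overall_tpr = m$overall_tpr, fdp = m$fdp,
      overall_tpr_se = m$overall_tpr_se, fdp_se = m$fdp_se,
      reps = m$reps)
  })
  estimation <- purrr::map_dfr(cells, function(m) {
    dplyr::mutate(
      dplyr::select(m$per_mediator, "index", "alpha_beta_true",
                    "mean_est", "mse", "mean_est_selected", "mse_selected",
                    "n_selected"),
      n = m$config$n, p = m$config$p, rho = m$config$rho,
      test_method = m$test_method, adjustment = m$adjustment,
      reps = m$reps)
  })
  structure(list(selection = selection, estimation = estimation,
                 cells = cells, reps = reps, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d cells x %d replications\n",
              length(x$cells), x$reps))
  print(dplyr::distinct(dplyr::select(
    x$selection, "n", "p", "rho", "test_method", "adjustment",
    "overall_tpr", "fdp")))
  invisible(x)
}
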
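# ggplot2 views of the fitted objects.

#' Plot propensity-score overlap between exposure groups
#'
#' @param object a [fit_propensity()] result.
#' @param X the exposure vector the model was fitted on.
#' @param ... unused.
#' @return a ggplot: mirrored score densities for the two groups, the
#'   standard visual check of positivity/overlap before weighting.
#' @export
autoplot.propensity_fit <- function(object, X, ...) {
  df <- tibble(score = object$scores,
               group = factor(ifelse(X == 1, "exposed", "unexposed")))
  ggplot(df, aes(x = .data$score, fill = .data$group)) +
    geom_density(alpha = 0.45, colour = NA) +
    labs(x = "propensity score", y = "density", fill = NULL,
         title = "Propensity-score overlap") +
    theme_minimal()
}

#' Plot the screening statistic profile
#'
#' @param object a [screen_mediators()] result.
#' @param ... unused.
#' @return a ggplot of ranked screening statistics with the retained set
#'   highlighted and the cutoff at `d` marked.
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- dplyr::arrange(object$table, .data$rank)
  ggplot(df, aes(x = .data$rank, y = .data$statistic,
                 colour = .data$kept)) +
    geom_point(size = 0.8) +
    geom_vline(xintercept = object$d + 0.5, linetype = "dashed") +
    scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70")) +
    labs(x = "rank", y = "screening statistic |β|",
         colour = "kept",
         title = sprintf("Sure independence screening (%s), d = %d",
                         object$method, object$d)) +
    theme_minimal()
}

#' Plot mediation-test results
#'
#' @param object an [hdma()] result.
#' @param ... unused.
#' @return a ggplot of candidate mediation effects against the adjusted
#'   p-value / estimated FDR, significant calls highlighted.
#' @export
autoplot.hdma_result <- function(object, ...) {
  df <- object$report
  if (!nrow(df)) {
    return(ggplot() + labs(title = "No candidate mediators") + theme_minimal())
  }
  ylab <- if (object$test_method == "mhima2") "estimated FDR" else "BH-adjusted p"
  ggplot(df, aes(x = .data$alpha_beta, y = .data$p_adjusted,
                 colour = .data$significant)) +
    geom_point() +
    geom_hline(yintercept = object$level, linetype = "dashed") +
    scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey60")) +
    labs(x = "estimated mediation effect α̂β̂",
         y = ylab, colour = "significant",
         title = sprintf("%s + %s mediation calls", object$test_method,
                         object$adjustment)) +
    theme_minimal()
}

#' Plot benchmark true-positive rates
#'
#' @param object a [run_benchmark()] result.
#' @param ... unused.
#' @return a ggplot of per-mediator TPR by cell, faceted by scenario.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- dplyr::mutate(object$selection,
                      cell = paste(.data$test_method, .data$adjustment, sep = "+"),
                      scenario = sprintf("n=%d, p=%d, rho=%.2g",
                                         .data$n, .data$p, .data$rho))
  ggplot(df, aes(x = factor(.data$alpha_beta_true), y = .data$tpr,
                 group = .data$cell, colour = .data$cell)) +
    geom_line() + geom_point() +
    facet_wrap(~scenario) +
    labs(x = "true mediation effect", y = "TPR", colour = NULL,
         title = "Per-mediator true positive rate") +
    theme_minimal()
}
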
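# Confounding-controlled sure independence screening: reduce p mediators
# to d = floor(2n / log n) candidates ranked by the adjusted effect of
# M_k on Y (|beta_k|), optionally multiplied by |alpha_k|.

#' Screening dimension of sure independence screening
#'
#' `d = floor(2 n / log n)` with the natural log — the moderate scale the
#' screening step reduces to.
#'
#' @param n sample size (>= 3 so that `log(n) > 1`).
#' @return an integer.
#' @examples
#' sis_dimension(300)  # 105
#' sis_dimension(500)  # 160
#' @export
sis_dimension <- function(n) {
  assert_scalar_number(n, "n", lower = 3)
  as.integer(floor(2 * n / log(n)))
}

#' Two-step weighted estimate of a single mediator's outcome effect
#'
#' Step 1 fits the weighted sub-model `Y = a + gamma_w X + beta_k M_k + e`
#' and keeps the weighted exposure coefficient `gamma_w`. Step 2 removes
#' the exposure contribution, `ehat = Y - gamma_w X`, and regresses `ehat`
#' on `M_k` *without* weights (with intercept) to obtain `beta_k`, its
#' standard error and p-value.
#'
#' @param Y outcome vector.
#' @param X binary exposure.
#' @param m single mediator column (non-constant).
#' @param weights IPW or OW weights from [compute_weights()]; equal weights
#'   reduce the estimator to its unweighted version.
#' @return a one-row tibble: `estimate`, `std_error`, `statistic`,
#'   `p_value`, `gamma_w`.
#' @export
two_step_beta <- function(Y, X, m, weights) {
  if (sd(m) == 0) abort("mediator is constant; two-step estimator undefined")
  step1 <- weighted_linear_fit(Y, cbind(X = X, M = m), weights = weights)
  gamma_w <- step1$estimate[step1$term == "X"]
  ehat <- Y - gamma_w * X
  step2 <- weighted_linear_fit(ehat, cbind(M = m), weights = NULL, se = "naive")
  out <- step2[step2$term == "M", c("estimate", "std_error", "statistic", "p_value")]
  out$gamma_w <- gamma_w
  out
}

# Vectorised engine: per-mediator OLS slope of a residualised outcome on a
# residualised mediator column, for all p columns at once. D is the shared
# nuisance design (already including intercept); returns estimate/se/p with
# df = n - ncol(D) - 1.
partial_slopes <- function(y, M, D) {
  qd <- qr(D)
  ry <- qr.resid(qd, y)
  RM <- qr.resid(qd, M)
  sxx <- colSums(RM^2)
  if (any(sxx <= 0)) abort("constant mediator column after adjustment")
  est <- colSums(RM * ry) / sxx
  df <- length(y) - ncol(D) - 1L
  rss <- pmax(sum(ry^2) - est^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  p <- 2 * stats::pt(-abs(stat), df)
  list(estimate = est, std_error = se, statistic = stat, p_value = p, df = df)
}

# Vectorised two-step weighted estimator over all mediator columns.
# Step 1 solves the 3-parameter weighted regression Y ~ 1 + X + M_k for
# every k via closed-form 3x3 systems; step 2 is the unweighted simple
# regression of (Y - gamma_k X) on M_k.
two_step_beta_all <- function(Y, X, M, w) {
  n <- length(Y)
  sw <- sum(w); swx <- sum(w * X); swy <- sum(w * Y)
  swxx <- sum(w * X * X); swxy <- sum(w * X * Y)
  swm <- colSums(w * M); swmm <- colSums(w * M^2)
  swxm <- colSums((w * X) * M); swmy <- colSums((w * Y) * M)
  p <- ncol(M)
  gamma_w <- numeric(p)
  for (k in seq_len(p)) {
    A <- matrix(c(sw,      swx,     swm[k],
                  swx,     swxx,    swxm[k],
                  swm[k],  swxm[k], swmm[k]), 3, 3)
    b <- c(swy, swxy, swmy[k])
    gamma_w[k] <- solve(A, b)[2]
  }
  # step 2: slope of (Y - gamma_k X) on M_k with intercept, unweighted
  my <- mean(Y); mx <- mean(X); mm <- colMeans(M)
  cm <- sweep(M, 2L, mm)
  sxx <- colSums(cm^2)
  s_my <- colSums(cm * (Y - my))
  s_mx <- colSums(cm * (X - mx))
  est <- (s_my - gamma_w * s_mx) / sxx
  # residual variance of step 2 per mediator
  yk_var <- sum((Y - my)^2) - 2 * gamma_w * sum((Y - my) * (X - mx)) +
    gamma_w^2 * sum((X - mx)^2)
  rss <- pmax(yk_var - est^2 * sxx, 0)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  list(estimate = est, std_error = se,
       statistic = stat, p_value = 2 * stats::pt(-abs(stat), df),
       gamma_w = gamma_w)
}

# Per-mediator exposure effects alpha_k under a given adjustment, for all
# columns at once. RA: M_k ~ 1 + X + C; PSR: M_k ~ 1 + X + PS;
# IPW/OW: weighted fit of M_k ~ 1 + X + C with robust or naive SEs.
alpha_all <- function(dataset, adjustment, ps_fit = NULL, weights = NULL,
                      se = "robust") {
  X <- dataset$X; M <- dataset$M; C <- dataset$C
  if (adjustment == "ra") {
    # alpha_k is the coefficient on X: residualise M and X on (1, C) and
    # take per-column simple slopes (Frisch-Waugh).
    D <- cbind(1, C)
    qd <- qr(D)
    rx <- qr.resid(qd, X)
    RM <- qr.resid(qd, M)
    return(slope_inference(rx, RM, df = length(X) - ncol(D) - 1L))
  }
  if (adjustment == "psr") {
    D <- cbind(1, ps_fit$scores)
    qd <- qr(D)
    rx <- qr.resid(qd, X)
    RM <- qr.resid(qd, M)
    return(slope_inference(rx, RM, df = length(X) - ncol(D) - 1L))
  }
  # weighted schemes: weighted regression of each M_k on (1, X, C)
  w <- as.numeric(weights)
  D <- cbind(1, X, C)
  xtw <- t(D * w)
  bread <- solve(xtw %*% D)
  B <- bread %*% (xtw %*% M)            # coefficients, one column per mediator
  est <- B[2, ]
  fitted <- D %*% B
  R <- M - fitted
  if (se == "robust") {
    # sandwich variance of the X coefficient for each mediator
    b2 <- bread[2, , drop = FALSE]       # 1 x (q+2)
    h <- drop(b2 %*% t(D * w))           # length-n influence weights
    v <- drop((h^2) %*% R^2)
    se_vec <- sqrt(v)
  } else {
    df <- nrow(D) - ncol(D)
    sigma2 <- colSums(w * R^2) / df
    se_vec <- sqrt(sigma2 * bread[2, 2])
  }
  stat <- ifelse(se_vec > 0, est / se_vec, 0)
  list(estimate = est, std_error = se_vec, statistic = stat,
       p_value = 2 * pnorm(-abs(stat)))
}

# OLS slope inference of each column of RM on the single regressor rx
# (both already residualised on the nuisance design).
slope_inference <- function(rx, RM, df) {
  sxx <- sum(rx^2)
  est <- colSums(RM * rx) / sxx
  rss <- pmax(colSums(RM^2) - est^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  list(estimate = est, std_error = se, statistic = stat,
       p_value = 2 * stats::pt(-abs(stat), df))
}

#' Screen mediators by adjusted outcome effect
#'
#' Computes, for every mediator, the confounding-adjusted effect of `M_k`
#' on `Y` — via ordinary regression with confounders (`ra`), with the
#' propensity score as the single covariate (`psr`), or via the two-step
#' weighted estimator (`ipw`, `ow`) — and keeps the `d` mediators with the
#' largest `|beta_k|` (or `|alpha_k beta_k|` with `basis = "alpha_beta"`).
#' Ties break by ascending mediator index.
#'
#' @param dataset a [mediation_dataset()].
#' @param adjustment `"ra"`, `"psr"`, `"ipw"` or `"ow"`.
#' @param basis `"beta"` (default) ranks by `|beta_k|`; `"alpha_beta"`
#'   multiplies in `|alpha_k|` from the matching mediator model.
#' @param d target dimension; defaults to [sis_dimension()] of the sample
#'   size, capped at `p`.
#' @param ps_fit optional pre-computed [fit_propensity()] result.
#' @return an object of class `screen_result`: a list with `table` (tibble
#'   of mediator, statistic, beta, se, p, rank, kept), `kept` (integer
#'   indices, ranked), `d`, `method`, `basis` and the propensity objects
#'   used. `tidy()` returns the table.
#' @export
screen_mediators <- function(dataset,
                             adjustment = c("ow", "ipw", "psr", "ra"),
                             basis = c("beta", "alpha_beta"),
                             d = NULL, ps_fit = NULL) {
  adjustment <- match.arg(adjustment)
  basis <- match.arg(basis)
  stopifnot(inherits(dataset, "mediation_dataset"))
  assert_binary(dataset$X, "X", require_both = TRUE)
  n <- length(dataset$X); p <- ncol(dataset$M)
  d <- as.integer(d %||% sis_dimension(n))
  d <- min(d, p)

  weights <- NULL
  if (adjustment %in% c("psr", "ipw", "ow") && is.null(ps_fit)) {
    ps_fit <- fit_propensity(dataset$C, dataset$X)
  }
  if (adjustment %in% c("ipw", "ow")) {
    weights <- compute_weights(ps_fit, dataset$X, scheme = adjustment)
  }

  beta <- switch(adjustment,
    ra = {
      D <- cbind(1, dataset$X, dataset$C)
      partial_slopes(dataset$Y, dataset$M, D)
    },
    psr = {
      D <- cbind(1, dataset$X, ps_fit$scores)
      partial_slopes(dataset$Y, dataset$M, D)
    },
    two_step_beta_all(dataset$Y, dataset$X, dataset$M, as.numeric(weights)))

  statistic <- abs(beta$estimate)
  alpha <- NULL
  if (basis == "alpha_beta") {
    alpha <- alpha_all(dataset, adjustment, ps_fit = ps_fit, weights = weights)
    statistic <- statistic * abs(alpha$estimate)
  }
  if (any(!is.finite(statistic))) abort("non-finite screening statistic")

  ord <- order(-statistic, seq_len(p))  # ties: ascending mediator index
  kept <- ord[seq_len(d)]
  rank_of <- integer(p); rank_of[ord] <- seq_len(p)
  beta_est <- unname(beta$estimate)
  beta_se <- unname(beta$std_error)
  p_beta <- unname(beta$p_value)
  tab <- tibble(
    mediator = dataset$mediator_ids,
    index = seq_len(p),
    statistic = unname(statistic),
    beta = beta_est,
    beta_se = beta_se,
    p_beta = p_beta,
    rank = rank_of,
    kept = seq_len(p) %in% kept
  )
  if (!is.null(alpha)) tab$alpha <- unname(alpha$estimate)
  structure(list(table = tab, kept = kept, d = d, method = adjustment,
                 basis = basis, ps_fit = ps_fit, weights = weights),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s / basis %s: kept %d of %d mediators\n",
              x$method, x$basis, x$d, nrow(x$table)))
  print(head(dplyr::arrange(x$table[x$table$kept, ], .data$rank), 5))
  invisible(x)
}

#' @export
tidy.screen_result <- function(x, ...) x$table

#' @export
glance.screen_result <- function(x, ...) {
  tibble(method = x$method, basis = x$basis, p = nrow(x$table), d = x$d)
}
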
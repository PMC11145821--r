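# Minimax-concave-penalty selection on the screened candidates.
# Coordinate descent on the standardized design with unpenalized exposure
# and covariate columns; lambda chosen by BIC (default) or AIC.

#' Minimax concave penalty function
#'
#' `P(b) = lambda (|b| - b^2 / (2 lambda delta))` for `|b| < delta lambda`,
#' and the constant plateau `lambda^2 delta / 2` beyond; continuous at the
#' join, so large coefficients incur no additional shrinkage.
#'
#' @param beta coefficient value(s).
#' @param lambda regularisation parameter (> 0).
#' @param delta concavity parameter (> 0); `delta -> Inf` recovers the
#'   Lasso penalty.
#' @return penalty value(s), vectorised over `beta`.
#' @examples
#' mcp_penalty(1.5, lambda = 1, delta = 3)  # 1.125
#' @export
mcp_penalty <- function(beta, lambda, delta) {
  assert_scalar_number(lambda, "lambda", lower = 0, closed_lower = FALSE)
  assert_scalar_number(delta, "delta", lower = 0, closed_lower = FALSE)
  b <- abs(beta)
  ifelse(b < delta * lambda,
         lambda * (b - b^2 / (2 * lambda * delta)),
         lambda^2 * delta / 2)
}

# Firm-threshold coordinate update for a standardized coordinate
# (x'x/n = 1): z is the univariate least-squares target.
mcp_update <- function(z, lambda, delta) {
  if (abs(z) <= delta * lambda) {
    s <- sign(z) * max(abs(z) - lambda, 0)
    s / (1 - 1 / delta)
  } else {
    z
  }
}

#' MCP-penalized outcome model on screened mediators
#'
#' Solves the penalized least-squares outcome model
#' `Y ~ X + M_screened + covariates` where the mediator coefficients carry
#' the minimax concave penalty and the exposure and covariates are
#' unpenalized. Columns are standardized internally and estimates returned
#' on the original scale. The regularisation parameter is chosen by BIC
#' (default) or AIC over a log-spaced grid.
#'
#' @param Y outcome vector.
#' @param X binary exposure.
#' @param M_screened `n x d` matrix of screened mediators (`d < n`).
#' @param covariates confounder matrix or propensity-score column entered
#'   unpenalized; `NULL` for none.
#' @param lambda_grid optional decreasing lambda sequence; default 100
#'   log-spaced values from the smallest lambda that zeroes every mediator
#'   down to 1/1000 of it.
#' @param delta MCP concavity parameter (default 3).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param weights optional positive observation weights.
#' @param dfmax stop the path once more than `dfmax` mediators are active
#'   (default `ceiling(n / log(n))`, half the screening dimension):
#'   information-criterion selection never favours such dense models in a
#'   sparse-mediation setting, and the dense tail of the path dominates
#'   the runtime.
#' @return an object of class `mcp_fit`: `coefficients` (length-d mediator
#'   coefficients, original scale), `selected` (indices with non-zero
#'   coefficients), `lambda`, `delta`, `criterion`, `intercept`,
#'   `unpenalized` (exposure/covariate coefficients), `path` tibble
#'   (lambda, df, criterion value) and `objective_trace` of the selected
#'   fit (non-increasing across sweeps).
#' @export
fit_mcp <- function(Y, X, M_screened, covariates = NULL, lambda_grid = NULL,
                    delta = 3, criterion = c("bic", "aic"), weights = NULL,
                    dfmax = NULL) {
  criterion <- match.arg(criterion)
  assert_scalar_number(delta, "delta", lower = 1, closed_lower = FALSE)
  M_screened <- as.matrix(M_screened)
  n <- length(Y); d <- ncol(M_screened)
  if (d >= n) {
    abort(sprintf("d = %d screened mediators with n = %d samples; MCP needs d < n — rerun screening with a smaller d", d, n))
  }
  U <- cbind(X = X, covariates)   # unpenalized block
  Z <- cbind(M_screened, U)
  pen <- c(rep(TRUE, d), rep(FALSE, ncol(U)))
  if (!is.null(weights)) {
    w <- sqrt(as.numeric(weights))
    Z <- Z * w; Yw <- Y * w
  } else {
    Yw <- Y
  }
  # standardize: center all columns and y, scale to sd 1 (population sd)
  ctr <- colMeans(Z); Zc <- sweep(Z, 2L, ctr)
  scl <- sqrt(colSums(Zc^2) / n)
  if (any(scl == 0)) abort("constant column in the penalized design")
  Zs <- sweep(Zc, 2L, scl, `/`)
  ybar <- mean(Yw); yc <- Yw - ybar

  G <- crossprod(Zs) / n
  cvec <- drop(crossprod(Zs, yc)) / n
  yty <- sum(yc^2) / n

  lam_max <- max(abs(cvec[pen]))
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = 100))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  dfmax <- as.integer(dfmax %||% ceiling(n / log(n)))
  b <- numeric(ncol(Zs))
  path <- vector("list", length(lambda_grid))
  best <- list(score = Inf)
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    sol <- mcp_cd(G, cvec, yty, b, pen, lam, delta)
    if (sum(sol$b[pen] != 0) > dfmax) break  # dense tail of the path
    b <- sol$b
    rss_n <- max(yty - 2 * sum(b * cvec) + drop(t(b) %*% G %*% b), 1e-12)
    df <- sum(b != 0) + 1L   # + intercept
    score <- n * log(rss_n) + df * (if (criterion == "bic") log(n) else 2)
    path[[li]] <- tibble(lambda = lam, df = df, score = score,
                         n_selected = sum(b[pen] != 0))
    if (score < best$score) {
      best <- list(score = score, lambda = lam, b = b, trace = sol$trace)
    }
  }
  b_orig <- best$b / scl
  coefs <- b_orig[seq_len(d)]
  names(coefs) <- colnames(M_screened) %||% paste0("M", seq_len(d))
  unpen <- b_orig[-seq_len(d)]
  names(unpen) <- colnames(U) %||% paste0("U", seq_along(unpen))
  intercept <- ybar - sum(ctr * b_orig)
  structure(list(
    coefficients = coefs,
    selected = which(coefs != 0),
    lambda = best$lambda, delta = delta, criterion = criterion,
    intercept = intercept, unpenalized = unpen,
    path = bind_rows(path), objective_trace = best$trace
  ), class = "mcp_fit")
}

# Coordinate descent for one lambda. The working set holds the
# unpenalized block plus every non-zero penalized coordinate; cycles run
# on the working-set Gram submatrix only, then one vectorised
# Karush-Kuhn-Tucker check over all coordinates admits violators. Returns
# the solution and the per-cycle objective trace (non-increasing for
# delta > 1 on a standardized design).
mcp_cd <- function(G, cvec, yty, b, pen, lambda, delta,
                   tol = 1e-8, max_outer = 100L, max_sweeps = 1000L) {
  objective <- function(b) {
    0.5 * (yty - 2 * sum(b * cvec) + sum(b * drop(G %*% b))) +
      sum(mcp_penalty(b[pen], lambda, delta))
  }
  trace <- objective(b)
  admitted <- integer(0)
  for (outer in seq_len(max_outer)) {
    active <- union(which(b != 0 | !pen), admitted)
    GA <- G[active, active, drop = FALSE]
    sol <- .cd_sweeps(GA, cvec[active], b[active], pen[active],
                      lambda, delta, tol, max_sweeps)
    bA <- sol$b
    b[active] <- bA
    trace <- c(trace, objective(b))
    # KKT check over all coordinates (vectorised)
    z_all <- cvec - drop(G[, active, drop = FALSE] %*% bA) + b
    viol <- which(pen & b == 0 & abs(z_all) > lambda + tol)
    viol <- setdiff(viol, active)
    if (!length(viol)) break
    admitted <- union(admitted,
                      viol[order(-abs(z_all[viol]))][1:min(length(viol), 10L)])
  }
  list(b = b, trace = trace)
}

#' @export
print.mcp_fit <- function(x, ...) {
  cat(sprintf("<mcp_fit> delta = %g, lambda = %.4g (%s), %d of %d mediators selected\n",
              x$delta, x$lambda, x$criterion, length(x$selected),
              length(x$coefficients)))
  invisible(x)
}

#' @export
tidy.mcp_fit <- function(x, ...) {
  tibble(mediator = names(x$coefficients),
         estimate = unname(x$coefficients),
         selected = x$coefficients != 0)
}

#' @export
glance.mcp_fit <- function(x, ...) {
  tibble(lambda = x$lambda, delta = x$delta, criterion = x$criterion,
         n_selected = length(x$selected))
}
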
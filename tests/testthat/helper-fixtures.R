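# Small fixtures built in code, shared across test files.

# A compact analysis-ready dataset under the default study conditions.
small_dataset <- function(n = 150, p = 60, rho = 0, seed = 42) {
  sim_dataset(sim_config(n = n, p = p, rho = rho), seed = seed)
}

# Deterministic confounders + exposure pair for propensity tests.
ps_fixture <- function(n = 200, seed = 7) {
  C <- sim_confounders(n, seed = seed)
  X <- sim_exposure(C, seed = seed + 1)
  list(C = C, X = X)
}

# Independently coded iteratively-reweighted-least-squares logistic fit,
# used as the oracle for fit_propensity().
irls_logistic <- function(X_design, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X_design))
  for (i in seq_len(max_iter)) {
    eta <- drop(X_design %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    beta_new <- solve(crossprod(X_design, X_design * W),
                      crossprod(X_design, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}
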
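test_that("confounder generator matches its stated distribution", {
  C <- sim_confounders(1e5, seed = 1)
  expect_equal(dim(C), c(1e5, 8))
  # continuous block: unit variances, 0.3 pairwise correlation
  expect_equal(unname(cor(C[, 1], C[, 2])), 0.3, tolerance = 0.01 / 0.3)
  expect_equal(unname(apply(C[, 1:4], 2, sd)), rep(1, 4), tolerance = 0.02)
  # binary block: Bernoulli(0.3)
  expect_true(all(C[, 5:8] %in% c(0, 1)))
  expect_lt(abs(mean(C[, 5]) - 0.3), 0.005)
  # determinism and argument validation
  expect_identical(sim_confounders(50, seed = 9), sim_confounders(50, seed = 9))
  expect_error(sim_confounders(1), "n")
})

test_that("exposure model is the stated intercept-free logistic", {
  C0 <- matrix(0, 100, 8)
  # all-zero confounders: P(X = 1) = 1/2 exactly; check via a large draw
  X0 <- sim_exposure(C0[rep(1, 1e4), ], seed = 3)
  expect_lt(abs(mean(X0) - 0.5), 0.02)

  C <- sim_confounders(1e5, seed = 2)
  X <- sim_exposure(C, seed = 4)
  # Monte-Carlo integration of the same logistic model on the same draw
  expected <- mean(plogis(drop(C %*% c(0.2, 0.2, 0.3, 0.3, 0.2, 0.2, 0.3, 0.3))))
  expect_lt(abs(mean(X) - expected), 0.005)

  # zero coefficients: marginally Bernoulli(1/2)
  Xnull <- sim_exposure(C[1:1e4, ], theta = rep(0, 8), seed = 5)
  expect_lt(abs(mean(Xnull) - 0.5), 0.02)

  expect_error(sim_exposure(C[, 1:5], seed = 1), "columns")
})

test_that("mediator generator has the configured error structure", {
  # no signal, independent errors: off-diagonal correlations near zero
  cfg0 <- sim_config(n = 1e4, p = 10, rho = 0,
                     alpha = rep(0, 10), beta = rep(0, 10), phi = rep(0, 8))
  C <- sim_confounders(1e4, seed = 11)
  X <- sim_exposure(C, seed = 12)
  M0 <- sim_mediators(X, C, cfg0, seed = 13)
  offdiag <- cor(M0)[upper.tri(diag(10))]
  expect_lt(max(abs(offdiag)), 0.05)
  # independent-branch errors carry the configured variance (1.2)
  expect_equal(mean(apply(M0, 2, var)), 1.2, tolerance = 0.05)

  # autocorrelated errors: adjacent correlation ~ rho
  cfg5 <- sim_config(n = 1e4, p = 10, rho = 0.5,
                     alpha = rep(0, 10), beta = rep(0, 10), phi = rep(0, 8))
  M5 <- sim_mediators(X, C, cfg5, seed = 14)
  adj <- vapply(1:9, function(k) cor(M5[, k], M5[, k + 1]), numeric(1))
  expect_lt(max(abs(adj - 0.5)), 0.03)
  expect_equal(mean(apply(M5, 2, var)), 1, tolerance = 0.05)

  # ordinary-least-squares oracle recovers alpha_1 = 0.4 at large n
  cfg <- sim_config(n = 1e4, p = 8)
  M <- sim_mediators(X, C, cfg, seed = 15)
  ols <- lm(M[, 1] ~ X + C)
  expect_equal(unname(coef(ols)["X"]), 0.4, tolerance = 0.03 / 0.4)

  expect_error(sim_config(n = 100, p = 10, rho = 1), "rho")
  expect_error(sim_config(n = 100, p = 10, rho = -0.1), "rho")
})

test_that("outcome generator follows the linear model with unit noise", {
  C <- sim_confounders(1e5, seed = 21)
  X <- sim_exposure(C, seed = 22)
  cfg_null <- sim_config(n = 1e5, p = 4, alpha = rep(0, 4), beta = rep(0, 4),
                         eta = rep(0, 8), gamma = 0)
  M <- sim_mediators(X, C, cfg_null, seed = 23)
  Y0 <- sim_outcome(X, M, C, cfg_null, seed = 24)
  expect_equal(var(Y0), 1, tolerance = 0.02)

  cfg <- sim_config(n = 1e4, p = 8)
  C2 <- C[1:1e4, ]; X2 <- X[1:1e4]
  M2 <- sim_mediators(X2, C2, cfg, seed = 25)
  Y <- sim_outcome(X2, M2, C2, cfg, seed = 26)
  ols <- lm(Y ~ X2 + M2 + C2)
  expect_equal(unname(coef(ols)["M2M4"]), 0.6, tolerance = 0.05 / 0.6)

  expect_identical(sim_outcome(X2, M2, C2, cfg, seed = 9),
                   sim_outcome(X2, M2, C2, cfg, seed = 9))
  expect_error(sim_outcome(X2, M2[1:10, ], C2, cfg), "dimension")
})

test_that("truth labelling exposes the sparse effect structure", {
  cfg <- sim_config(n = 100, p = 20)
  truth <- sim_truth(cfg)
  expect_equal(truth$alpha_beta[1:4], c(0.16, 0.20, 0.25, 0.30))
  expect_identical(which(truth$true_mediator), 1:4)
  # indices 5-6: exposure path only; 7-8: outcome path only
  expect_true(all(truth$alpha[5:6] != 0) && all(truth$beta[5:6] == 0))
  expect_true(all(truth$alpha[7:8] == 0) && all(truth$beta[7:8] != 0))
  expect_true(all(truth$alpha_beta[9:20] == 0))
})

test_that("null-mediator correlations sit in the stated band under defaults", {
  cfg <- sim_config(n = 1e4, p = 50)
  dat <- sim_dataset(cfg, seed = 31)
  cors <- cor(dat$M[, 9:50])  # null mediators share only the confounder signal
  mean_abs <- mean(abs(cors[upper.tri(cors)]))
  expect_gt(mean_abs, 0.15)
  expect_lt(mean_abs, 0.35)
})

test_that("one master seed reproduces a full dataset bit-identically", {
  cfg <- sim_config(n = 80, p = 30)
  d1 <- sim_dataset(cfg, seed = 99)
  d2 <- sim_dataset(cfg, seed = 99)
  expect_identical(d1$C, d2$C)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$M, d2$M)
  expect_identical(d1$Y, d2$Y)
  # RNG streams are split per component: a different p leaves X unchanged
  d3 <- sim_dataset(sim_config(n = 80, p = 50), seed = 99)
  expect_identical(d1$X, d3$X)
  expect_identical(d1$C, d3$C)
})
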
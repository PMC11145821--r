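test_that("screening dimension follows floor(2n / log n)", {
  expect_identical(sis_dimension(300), 105L)
  expect_identical(sis_dimension(500), 160L)
  expect_error(sis_dimension(2), "n")
  # capped at p inside the screener
  dat <- small_dataset(n = 150, p = 20)
  scr <- screen_mediators(dat, "ra")
  expect_identical(scr$d, 20L)
  expect_identical(sort(scr$kept), 1:20)
})

test_that("two-step estimator reduces correctly in degenerate cases", {
  set.seed(301)
  n <- 400
  X <- rbinom(n, 1, 0.5)
  m <- rnorm(n)
  Y <- 0.5 * X + 0.6 * m + rnorm(n)

  # equal weights: identical to the unweighted two-step computation
  res_w <- two_step_beta(Y, X, m, weights = rep(2, n))
  step1 <- lm(Y ~ X + m)
  ehat <- Y - coef(step1)["X"] * X
  res_u <- lm(ehat ~ m)
  expect_equal(res_w$estimate, unname(coef(res_u)["m"]), tolerance = 1e-10)

  # exposure orthogonal to outcome and mediator: residualisation is a no-op
  Y2 <- 0.6 * m + rnorm(n)
  res2 <- two_step_beta(Y2, X, m, weights = rep(1, n))
  expect_equal(res2$estimate, unname(coef(lm(Y2 ~ m))["m"]), tolerance = 0.02)

  expect_error(two_step_beta(Y, X, rep(1, n), rep(1, n)), "constant")
})

test_that("vectorised two-step engine agrees with the per-mediator version", {
  dat <- small_dataset(n = 120, p = 12)
  fit <- fit_propensity(dat$C, dat$X)
  w <- compute_weights(fit, dat$X, "ow")
  all_res <- owmediate:::two_step_beta_all(dat$Y, dat$X, dat$M, as.numeric(w))
  for (k in c(1, 5, 12)) {
    single <- two_step_beta(dat$Y, dat$X, dat$M[, k], w)
    expect_equal(unname(all_res$estimate[k]), single$estimate, tolerance = 1e-8)
    expect_equal(unname(all_res$std_error[k]), single$std_error, tolerance = 1e-8)
  }
})

test_that("two-step consistency: OW recovers the mediator effect at scale", {
  # The two-step statistic adjusts the exposure path by weighting but
  # never enters C in its outcome step, so it is only consistent for
  # beta when the mediator-outcome relation is not confounded by C
  # (phi = eta = 0). With confounded mediators it is a ranking statistic,
  # biased by the shared confounder signal.
  cfg1 <- sim_config(n = 5000, p = 1, alpha = 0.4, beta = 0.4,
                     phi = rep(0, 8), eta = rep(0, 8))
  dat1 <- sim_dataset(cfg1, seed = 34)
  fit1 <- fit_propensity(dat1$C, dat1$X)
  ow1 <- compute_weights(fit1, dat1$X, "ow")
  res <- two_step_beta(dat1$Y, dat1$X, dat1$M[, 1], ow1)
  expect_lt(abs(res$estimate - 0.4), 0.05)

  # IPW and OW agree on large samples without extreme scores, including
  # under the fully confounded study conditions
  ipw1 <- compute_weights(fit1, dat1$X, "ipw")
  res_ipw <- two_step_beta(dat1$Y, dat1$X, dat1$M[, 1], ipw1)
  expect_lt(abs(res$estimate - res_ipw$estimate), 0.03)

  cfg2 <- sim_config(n = 1e4, p = 4)
  dat2 <- sim_dataset(cfg2, seed = 35)
  fit2 <- fit_propensity(dat2$C, dat2$X)
  b_ow <- two_step_beta(dat2$Y, dat2$X, dat2$M[, 1],
                        compute_weights(fit2, dat2$X, "ow"))
  b_ipw <- two_step_beta(dat2$Y, dat2$X, dat2$M[, 1],
                         compute_weights(fit2, dat2$X, "ipw"))
  expect_lt(abs(b_ow$estimate - b_ipw$estimate), 0.03)
})

test_that("screener ranks by |statistic| with deterministic tie-breaking", {
  dat <- small_dataset(n = 150, p = 30)
  # duplicate a column: identical statistics must keep ascending index order
  dat$M[, 30] <- dat$M[, 7]
  scr <- screen_mediators(dat, "ra", d = 10)
  tab <- scr$table
  expect_equal(tab$rank[order(-tab$statistic, tab$index)], 1:30)
  r7 <- tab$rank[7]; r30 <- tab$rank[30]
  expect_identical(r30, r7 + 1L)
  # kept set respects the ranking
  expect_setequal(scr$kept, tab$index[tab$rank <= 10])
})

test_that("screening is invariant to mediator column permutation", {
  dat <- small_dataset(n = 150, p = 25)
  perm <- sample(25)
  dat_p <- dat
  dat_p$M <- dat$M[, perm]
  dat_p$mediator_ids <- dat$mediator_ids[perm]
  scr <- screen_mediators(dat, "ow", d = 8)
  scr_p <- screen_mediators(dat_p, "ow", d = 8)
  expect_setequal(dat$mediator_ids[scr$kept], dat_p$mediator_ids[scr_p$kept])
  expect_equal(sort(scr$table$statistic), sort(scr_p$table$statistic),
               tolerance = 1e-10)
})

test_that("true mediators survive screening at the study's sample sizes", {
  cfg <- sim_config(n = 500, p = 1000)
  retained <- vapply(1:10, function(r) {
    dat <- sim_dataset(cfg, seed = 400 + r)
    scr <- screen_mediators(dat, "ow")
    all(1:4 %in% scr$kept)
  }, logical(1))
  expect_gte(mean(retained), 0.9)
})

test_that("all four adjustments and both bases produce valid screens", {
  dat <- small_dataset(n = 150, p = 40)
  for (adj in c("ra", "psr", "ipw", "ow")) {
    scr <- screen_mediators(dat, adj, d = 15)
    expect_length(scr$kept, 15)
    expect_true(all(is.finite(scr$table$statistic)))
  }
  scr_ab <- screen_mediators(dat, "ow", basis = "alpha_beta", d = 15)
  expect_true("alpha" %in% names(scr_ab$table))
  expect_equal(scr_ab$table$statistic,
               abs(scr_ab$table$alpha * scr_ab$table$beta), tolerance = 1e-12)
})
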
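test_that("workflow runs are deterministic given one seed", {
  dat <- small_dataset(n = 150, p = 100, seed = 91)
  f1 <- hdma(dat, "mhima2", "ow", seed = 17)
  f2 <- hdma(dat, "mhima2", "ow", seed = 17)
  expect_identical(f1$report, f2$report)
  g1 <- hdma(dat, "hima", "ow", seed = 17)
  g2 <- hdma(dat, "hima", "ow", seed = 17)
  expect_identical(g1$report, g2$report)
})

test_that("a typical replication is dominated by the true mediators", {
  dat <- sim_dataset(sim_config(n = 500, p = 1000), seed = 92)
  fit <- hdma(dat, "mhima2", "ow", seed = 92)
  sig <- fit$report$index[fit$report$significant]
  expect_gte(sum(sig %in% 1:4), 3)
  expect_lte(length(setdiff(sig, 1:4)), 2)
  # report contract: product column and %TE defined for significant calls
  expect_equal(fit$report$alpha_beta,
               fit$report$alpha_hat * fit$report$beta_hat, tolerance = 1e-12)
  expect_true(all(!is.na(fit$report$percent_te[fit$report$significant])))
})

test_that("an all-null configuration yields no calls", {
  cfg <- sim_config(n = 300, p = 200,
                    alpha = rep(0, 200), beta = rep(0, 200))
  dat <- sim_dataset(cfg, seed = 93)
  fit <- hdma(dat, "mhima2", "ow", seed = 93)
  expect_identical(sum(fit$report$significant), 0L)
})

test_that("replication metrics follow their definitions", {
  truth <- sim_truth(sim_config(n = 100, p = 20))
  mk_report <- function(sig_idx, all_idx = 1:10) {
    tibble::tibble(index = all_idx,
                   alpha_beta = 0.1 * all_idx,
                   significant = all_idx %in% sig_idx)
  }
  # perfect single replication
  m1 <- evaluate_replications(list(mk_report(1:4)), truth)
  expect_identical(m1$overall_tpr, 1)
  expect_identical(m1$fdp, 0)

  # hand-computed two-replication example: {M1, M9} then {}
  m2 <- evaluate_replications(list(mk_report(c(1, 9)), mk_report(integer(0))),
                              truth)
  expect_equal(m2$per_mediator$tpr, c(0.5, 0, 0, 0))
  expect_equal(m2$overall_tpr, 0.125)
  expect_equal(m2$fdp, (1 / 2 + 0) / 2)

  # invariance to replication order
  m2r <- evaluate_replications(list(mk_report(integer(0)), mk_report(c(1, 9))),
                               truth)
  expect_equal(m2$per_mediator, m2r$per_mediator)
  expect_equal(m2$fdp, m2r$fdp)

  expect_error(evaluate_replications(list(), truth), "at least one")
})

test_that("per-replication seeds are counter-based and order-independent", {
  seeds <- owmediate:::split_seed(123, 10, stream = 2)
  expect_identical(seeds[7], owmediate:::split_seed(123, 10, stream = 2)[7])
  cfg <- sim_config(n = 60, p = 10)
  # regenerating replication 3 alone matches its dataset inside a cell run
  d3 <- sim_dataset(cfg, seed = seeds[3])
  d3b <- sim_dataset(cfg, seed = owmediate:::split_seed(123, 10, stream = 2)[3])
  expect_identical(d3$Y, d3b$Y)
})

test_that("benchmark grid emits coherent tables at toy scale", {
  bench <- run_benchmark(
    scenarios = tibble::tibble(n = 100, p = 30, rho = 0),
    methods = tibble::tibble(test_method = c("mhima2", "hima"),
                             adjustment = "ow"),
    reps = 3, seed = 7)
  expect_s3_class(bench$selection, "tbl_df")
  expect_identical(nrow(bench$selection), 8L)  # 2 methods x 4 true mediators
  expect_true(all(bench$selection$tpr >= 0 & bench$selection$tpr <= 1))
  expect_true(all(bench$estimation$mse >= 0 | is.na(bench$estimation$mse)))
  expect_true(all(c("mean_est", "mse", "mean_est_selected") %in%
                    names(bench$estimation)))
})

test_that("delimited reader joins, drops and recodes correctly", {
  tmp <- withr::local_tempdir()
  dat <- small_dataset(n = 10, p = 4, seed = 95)
  pheno <- data.frame(id = dat$sample_ids, smoke = dat$X, fev = dat$Y,
                      dat$C[, 1:3])
  meds <- data.frame(id = dat$sample_ids, dat$M)
  write.table(pheno, file.path(tmp, "pheno.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(meds, file.path(tmp, "meds.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ds <- read_mediation_data(file.path(tmp, "pheno.tsv"),
                            file.path(tmp, "meds.tsv"),
                            exposure = "smoke", outcome = "fev",
                            confounders = c("C1", "C2", "C3"))
  expect_s3_class(ds, "mediation_dataset")
  expect_identical(dim(ds), c(10L, 4L))
  expect_equal(ds$Y, dat$Y)

  # one sample missing from the mediator file: dropped with a message
  write.table(meds[-3, ], file.path(tmp, "meds2.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_message(
    ds2 <- read_mediation_data(file.path(tmp, "pheno.tsv"),
                               file.path(tmp, "meds2.tsv"),
                               exposure = "smoke", outcome = "fev",
                               confounders = c("C1", "C2", "C3")),
    "dropped 1")
  expect_identical(length(ds2$X), 9L)

  # non-binary exposure is refused with the observed levels listed
  pheno$smoke[1] <- 2
  write.table(pheno, file.path(tmp, "pheno3.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(
    read_mediation_data(file.path(tmp, "pheno3.tsv"),
                        file.path(tmp, "meds.tsv"),
                        exposure = "smoke", outcome = "fev",
                        confounders = c("C1", "C2", "C3")),
    "levels")
})

test_that("tidiers and autoplots return the expected shapes", {
  dat <- small_dataset(n = 150, p = 60, seed = 96)
  fit <- hdma(dat, "mhima2", "ow", seed = 96)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(nrow(glance(fit)), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$screen), "ggplot")
  expect_s3_class(autoplot(fit$ps_fit, dat$X), "ggplot")
})
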
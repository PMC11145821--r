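# owmediate

Confounder-adjusted high-dimensional mediation analysis with overlap
weighting, for continuous outcomes.

## What problem this solves

Epigenome-wide association studies often ask whether a binary exposure
(e.g. smoking) affects a continuous outcome (e.g. lung function or an
immune-cell fraction) *through* DNA methylation: with p ≫ n candidate
CpG mediators M₁…M_p and confounders C, the working models are

    M_ik = a_k + α_k X_i + φ_k' C_i + e_ik
    Y_i  = a + γ X_i + β' M_i + η' C_i + ε_i

and mediator k carries the indirect effect α_k β_k. In observational
data both the dimension and the confounding must be handled. The
package implements a staged procedure:

1. **Confounding adjustment** — logistic propensity scores with four
   schemes: regression adjustment (`ra`), PS regression (`psr`),
   inverse probability weighting (`ipw`), and **overlap weighting**
   (`ow`; weights 1−π for exposed, π for unexposed — bounded, and
   exactly balancing confounder means under the ML logistic fit).
2. **Screening** — confounding-controlled sure independence screening
   to d = ⌊2n/log n⌋ candidates, ranked by the adjusted effect of M_k
   on Y (a two-step weighted statistic in the weighted schemes).
3. **Penalized estimation** — either minimax-concave-penalty (MCP)
   selection with BIC (the `hima` path) or de-biased-Lasso estimates
   with p-values for every screened candidate (the `mhima2` path).
4. **Mediation testing** — joint-significance (max-P) testing: BH
   adjustment under the uniform null (`hima`), or a pointwise FDR under
   the 3-component composite-null mixture
   {both effects null, only α null, only β null} (`mhima2`).

A fully parameterised synthetic-data generator reproduces the study
conditions of the accompanying simulation benchmark (8 confounders,
sparse true effects α·β = 0.16/0.20/0.25/0.30 for the four true
mediators, AR-correlated mediator errors), so every stage is testable
without any external data. A vignette
(`vignettes/ow-mediation-methods.Rmd`) documents the models, numerical
choices and limitations.

## Worked example

```r
library(owmediate)

cfg <- sim_config(n = 500, p = 1000)      # benchmark study conditions
dat <- sim_dataset(cfg, seed = 2024)
fit <- hdma(dat, test_method = "mhima2", adjustment = "ow", seed = 2024)
fit
#> <hdma_result> mhima2 + ow: n = 500, p = 1000, d = 160
#>   significant mediators at 0.05: 4
#> # A tibble: 4 × 6
#>   mediator alpha_hat beta_hat alpha_beta percent_te p_adjusted
#>   <chr>        <dbl>    <dbl>      <dbl>      <dbl>      <dbl>
#> 1 M4           0.456    0.597      0.272       21.8    0.00105
#> 2 M1           0.439    0.378      0.166       13.3    0.00345
#> 3 M3           0.342    0.459      0.157       12.6    0.0233
#> 4 M2           0.339    0.517      0.175       14.1    0.0233
```

The four true mediators (M1–M4) are recovered: `alpha_hat` and
`beta_hat` are the confounder-adjusted path estimates, `alpha_beta`
their product (the mediation effect; truth 0.16–0.30 here),
`percent_te` the share of the total exposure effect routed through that
mediator, and `p_adjusted` the estimated composite-null FDR at the
candidate's max-P value. `tidy(fit)` returns the full candidate table,
`glance(fit)` a one-row summary, `autoplot(fit)` the effect/FDR plot.

Real data enter through `read_mediation_data()` (delimited phenotype
table + sample-by-mediator matrix, inner-joined on sample id), or
directly via `mediation_dataset()`. A thin command-line wrapper with
`simulate`, `run` and `benchmark` subcommands is installed at
`inst/cli/owmediate.R`.

Replication studies use the same machinery:

```r
bench <- run_benchmark(
  scenarios = tibble::tibble(n = c(300, 500), p = 1000, rho = 0),
  methods   = tibble::tibble(test_method = c("mhima2", "hima"), adjustment = "ow"),
  reps = 100, seed = 1)
bench$selection   # per-mediator TPR, overall TPR, FDP per cell
bench$estimation  # Mean / MSE of the mediation-effect estimates
```

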
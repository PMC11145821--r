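---
title: "Methods: confounder-adjusted high-dimensional mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confounder-adjusted high-dimensional mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Epigenome-wide studies routinely ask whether an exposure (smoking, say)
acts on a health outcome (lung function, immune cell composition)
*through* DNA-methylation changes. With a binary exposure $X$, a
continuous outcome $Y$, $p \gg n$ candidate mediators
$M_1, \dots, M_p$ (CpG beta values) and $q$ baseline confounders $C$,
the working models are

$$M_{ik} = a_k + \alpha_k X_i + \phi_k^{\top} C_i + e_{ik},
\qquad
Y_i = a + \gamma X_i + \beta^{\top} M_i + \eta^{\top} C_i + \varepsilon_i,$$

and mediator $k$ carries a mediation (indirect) effect
$\alpha_k \beta_k$ under the product-of-coefficients definition. Two
things make this hard in observational data: the dimension of $M$, and
confounding of all three arrows ($X\!\to\!M$, $M\!\to\!Y$,
$X\!\to\!Y$). This package implements a four-stage procedure that deals
with both, in two variants:

* **hima** — propensity-score (PS) confounding adjustment, sure
  independence screening (SIS), minimax-concave-penalty (MCP) selection,
  joint-significance (max-P) testing with Benjamini–Hochberg correction
  under the uniform null reading;
* **mhima2** — the same adjustment and screening, then de-biased Lasso
  estimates with p-values for *all* screened candidates and
  joint-significance testing under a three-component composite-null
  mixture. This is the more powerful variant and the package default.

Either variant can run under four confounding adjustments: plain
regression adjustment (`ra`), PS regression (`psr`), inverse probability
weighting (`ipw`), and overlap weighting (`ow`). Overlap weights
($1-\pi_i$ for exposed, $\pi_i$ for unexposed) are bounded in $(0,1)$,
concentrate on subjects with genuine equipoise ($\pi \approx 0.5$), and
balance confounder means exactly between groups under a
maximum-likelihood logistic PS — the property that makes `ow` the
recommended default when PS tails are extreme.

# Stage by stage

## Propensity scores and weights

$\pi_i = P(X_i = 1 \mid C_i)$ is fitted by maximum-likelihood logistic
regression with intercept; fitted probabilities are clipped to
$[10^{-6}, 1-10^{-6}]$ before weight construction so IPW weights stay
finite (OW is unaffected). Non-convergence or separation is reported,
not silently accepted. `weight_diagnostics()` reports the weight range
and effective sample size $(\sum w)^2 / \sum w^2$.

All weighted regressions run through one engine
(`weighted_linear_fit()`). Standard errors default to the HC0 sandwich:
adjustment weights are not precision weights, so the classical WLS
variance has no justification here; the naive option is kept for
comparison.

## Screening

SIS reduces $p$ to $d = \lfloor 2n/\log n \rfloor$ candidates ($105$ at
$n=300$, $160$ at $n=500$), ranked by the magnitude of the adjusted
effect of $M_k$ on $Y$:

* `ra`: coefficient of $M_k$ in OLS of $Y$ on $(1, X, M_k, C)$;
* `psr`: same with the PS replacing $C$;
* `ipw`/`ow`: a two-step statistic — a weighted fit of
  $Y \sim 1 + X + M_k$ yields $\hat\gamma_{k,w}$, then
  $Y - \hat\gamma_{k,w} X$ is regressed on $M_k$ without weights.

The two-step statistic adjusts the exposure path by weighting but does
not enter $C$ in its second step; under mediator–outcome confounding it
is therefore a *ranking* statistic, biased upward by the shared
confounder signal, and consistent for $\beta_k$ only when that path is
clean. That is exactly the role screening needs: the bias is common
across mediators and does not reorder them. Ranking uses $|\beta_k|$ by
default; the $|\alpha_k \beta_k|$ basis is available but known to screen
poorly under confounding. Ties break by ascending mediator index so
results are platform-independent.

## Penalized estimation

Both penalized stages keep $X$ and the covariates ($C$, or the PS for
`psr`) unpenalized, and — in the weighted paths — fit the outcome model
with the scheme's weights (`weighted_penalized = TRUE`). This is the
scheme-consistent reading: weighting is how the adjustment reaches the
outcome stage, and it is the reading under which the package's benchmark
reproduces the reference operating characteristics; the unweighted
variant is a flag away.

**MCP.** $P_{\lambda,\delta}(\beta) = \lambda(|\beta| -
\beta^2/(2\lambda\delta))$ for $|\beta| < \delta\lambda$, constant
$\lambda^2\delta/2$ beyond. Coordinate descent runs on the standardized
Gram system with firm-threshold updates, a working-set strategy with a
vectorised KKT check, and a compiled inner loop; the objective is
recorded every cycle and is non-increasing. $\delta = 3$ (the
conventional concavity), $\lambda$ over 100 log-spaced values down to
$10^{-3}\lambda_{\max}$, chosen by BIC ($n \le 500$ favours the sparser
criterion; AIC is available). The path stops once more than
$\lceil n/\log n \rceil$ mediators (half the screening dimension) are
active: an information criterion never selects such dense models in a
sparse-mediation setting and the dense tail dominates runtime.
P-values for the selected set come from an OLS refit, mirroring the
original HIMA practice, and enter max-P testing with BH correction whose
family size is $d$ — unselected screened candidates count as tests that
were never significant.

**De-biased Lasso.** The initial fit is a Lasso of $Y$ on
$(X, M_{\mathrm{SIS}}, C)$ with 10-fold cross-validated $\lambda$
(deterministic folds from the pipeline seed) and $X$, $C$ unpenalized.
For each mediator column $j$, a nodewise Lasso of $Z_j$ on the remaining
columns gives the residualised direction $z_j$, and

$$\hat b_j = \hat\beta_j + \frac{z_j^{\top}(y - Z\hat\beta)}{z_j^{\top} Z_j},
\qquad
\widehat{se}_j = \hat\sigma_\varepsilon \frac{\lVert z_j \rVert_2}{\lvert z_j^{\top} Z_j \rvert},
\qquad
P_j = 2\{1 - \Phi(|\hat b_j| / \widehat{se}_j)\},$$

with $\hat\sigma_\varepsilon^2$ the residual sum of squares over
$n - \hat s$. The nodewise penalty is cross-validated on five evenly
spaced columns only, and the median $\lambda/\lambda_{\max}$ ratio is
carried to every column: with the screened dimension well below $n$ the
projection directions are insensitive to this choice, while runtime
stays flat in $d$. The tail probability is evaluated in the upper tail
(`lower.tail = FALSE`) so extreme statistics keep positive p-values.

## Mediation testing

$\alpha_k$ p-values come from the adjustment-matched mediator model
(weighted with robust SEs for `ipw`/`ow`). The raw mediation p-value is
$\max(P_{\alpha_k}, P_{\beta_k})$.

The **uniform-null** reading applies BH directly. The **mixture-null**
reading decomposes the composite null into: both effects null
($\pi_{00}$), only $\alpha$ null ($\pi_{01}$), only $\beta$ null
($\pi_{10}$). Marginal null fractions are estimated by Storey's method
at $\lambda = 0.5$ and combined under cross-independence. Expected false
positives at threshold $t$ are $q\pi_{00}t^2$ (both p-values must fall
below $t$) plus $q(\pi_{01} + \pi_{10})t$, treating the non-null
p-value as stochastically no larger than uniform — the estimator's
defining approximation. The pointwise FDR at each candidate's own raw
p-value is clipped to $[0,1]$ and given a step-up monotonicity pass so
calls are threshold-consistent. The printed composite-null components
use the standard decomposition; a version with overlapping components
(joined by "or") would make them non-disjoint and is treated as a typo.

Significance is 0.05 throughout (exposed as `level`). The percent of
total effect is
$100\,\hat\alpha_k\hat\beta_k / (\hat\gamma + \sum_j
\hat\alpha_j\hat\beta_j)$ over significant $j$.

# The synthetic-data generator

`sim_config()` / `sim_dataset()` reproduce the benchmark's study
conditions exactly: 8 confounders (4 multivariate normal with unit
variance and 0.3 correlation, 4 Bernoulli(0.3)); intercept-free
logistic exposure with
$\theta = (0.2,0.2,0.3,0.3,0.2,0.2,0.3,0.3)$; mediators with
$\alpha = (0.4,0.4,0.5,0.5,0.5,0.5,0,\dots)$, shared confounder effects
$\phi = \theta$, and per-mediator intercepts $a_k \sim U(0,1)$ drawn
once per replication; outcome with
$\beta = (0.4,0.5,0.5,0.6,0,0,0.5,0.5,0,\dots)$, $\gamma = 0.5$,
$\eta = \theta$, intercept 0.5 and unit normal noise. True mediators
are M1–M4 with effects $(0.16, 0.20, 0.25, 0.30)$; M5–M6 carry only the
exposure path and M7–M8 only the outcome path.

Two numerical readings were genuinely open and are fixed as follows:

* "errors from $N(0, 1.2)$" is read as **variance** 1.2. Under that
  reading the null-mediator pairwise correlation implied by the shared
  confounder signal is $0.537/(0.537+1.2) \approx 0.31$, inside the
  stated 0.15–0.35 band (the SD reading gives $\approx 0.27$, also
  inside; the variance reading is the default and the scale is
  exposed).
* with autocorrelation $\rho > 0$, error rows follow the
  **unit-diagonal** AR covariance $\rho^{|k-k'|}$, which reproduces the
  stated adjacent-mediator correlations ($\approx$ 0.5, 0.7, 0.8 at
  $\rho =$ 0.25, 0.5, 0.75); scaling that matrix by the error variance
  is available as a flag.

RNG streams are split per component (confounders, exposure, mediator
intercepts/errors, outcome noise), so changing $p$ does not perturb
$X$, and per-replication seeds are derived from a master seed by a
counter-based split — any replication can be regenerated alone and the
benchmark metrics do not depend on execution order.

What the generator does *not* emulate: beta-value boundedness in
$[0,1]$, probe-level measurement error, batch structure, cell-type
composition, or genomic dependence beyond the AR band. Passing the
benchmark therefore shows the inferential machinery behaves as designed
under the stated sampling model — not that real methylation data meet
its assumptions.

# Benchmark conventions

`run_cell()` / `run_benchmark()` summarise replications by: per-true-
mediator TPR, overall TPR (their mean), FDP (per-replication false
discoveries over $\max(\text{discoveries}, 1)$, with $0/0 = 0$,
averaged), and Mean/MSE of $\hat\alpha_k\hat\beta_k$. Mean/MSE average
over the replications in which the mediator carries an estimate, i.e.
entered the tested candidate set; conditioning on a significant call
instead (also reported, `*_selected` columns) inflates small effects
upward — the benchmark's reference values for the smallest effect sit
*below* its true value, which identifies the unconditional convention.
Monte-Carlo standard errors accompany the rate metrics
($\approx \sqrt{q(1-q)/\text{reps}}$).

The shipped tests run the p = 1000, rho = 0 cells at 100 replications
(Monte-Carlo SE on a TPR near 0.65 is about 0.05) and the global-null
calibration at 200 replications; those sizes put every cell's metrics
within the comparison bands while a full cell grid at 500 replications
remains a `run_benchmark()` call away.

# Known limitations

* Continuous outcomes only; no binary or survival outcomes.
* Parallel mediators (no causal ordering among $M_k$); sequential
  ignorability and positivity are assumed, and no sensitivity analysis
  for unmeasured confounding is provided.
* The two-step screening statistic is a ranking device, not a
  consistent estimator, under mediator–outcome confounding (see above).
* PS estimation is logistic-only by design; matching, stratification,
  trimming and machine-learning PS estimators are out of scope.
* The mixture-null FDR relies on the Storey marginals and
  cross-independence combination; heavy dependence between the
  $\alpha$- and $\beta$-p-value sets would distort $\hat\pi$.
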
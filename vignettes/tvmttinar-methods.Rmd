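---
title: "Models and methods in tvmttinar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tvmttinar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvmttinar)
```

## The model

Count time series — daily trade counts, case counts in surveillance, event
tallies — often show two kinds of structure that a plain INAR(1) model
misses: regime changes driven by the level of the series itself, and
autoregressive strength that drifts with observable external conditions.
`tvmttinar` implements a first-order threshold INAR process that combines
both. The recursion is

$$X_t = (\phi_{1,t} \circ X_{t-1})\,I_{1,t} +
        (\phi_{2,t} * X_{t-1})\,I_{2,t} + \epsilon_t,$$

where $\circ$ is binomial thinning ($\phi \circ X$ is a
Binomial$(X, \phi)$ draw), $*$ is negative-binomial thinning ($\phi * X$ is
a sum of $X$ i.i.d. geometric variables with success probability
$1/(1+\phi)$, hence mean $\phi X$ but variance $\phi(1+\phi)X$ — an
over-dispersed survival mechanism), and $\epsilon_t$ is
Poisson($\lambda$). The regime indicator compares the lagged count with an
integer threshold $r$: with orientation flag $R = 0$, regime 1 (binomial
thinning, coefficients $\beta_1$) is active when $X_{t-1} \le r$; $R = 1$
swaps the branches. Each thinning probability follows a logistic link in
observed explanatory variables,

$$\operatorname{logit} \phi_{i,t} = Z_t^\top \beta_i, \qquad
  Z_t = (1, Z_{1,t}, \dots, Z_{q,t})^\top,$$

so external conditions modulate the autoregressive strength over time. The
covariates are assumed stationary, observable, and independent of the past
of the count process. The process is strictly stationary and ergodic for
any coefficient values with a bounded linear predictor; the package relies
on that result rather than re-deriving it.

Mixing the two operators is not cosmetic: the two regimes differ in their
conditional *dispersion*, not just their mean, so a piecewise structure
remains identifiable even when $\beta_1 = \beta_2$ (a measure-zero case the
inference machinery deliberately ignores).

## Exact transition probabilities and simulation

One step of the chain is a thinning draw plus an independent Poisson
innovation, so the transition pmf is a finite convolution
(`transition_pmf()`), evaluated in log-space with log-gamma terms. Two
degenerate-input conventions matter:

* $X_{t-1} = 0$: thinning of zero is zero under either operator, so the
  transition reduces to the Poisson innovation pmf. (For the
  negative-binomial branch this is the empty-sum convention
  $\phi * 0 \equiv 0$; the gamma-ratio form of the pmf is undefined
  at $x = 0$.)
* The negative-binomial thinning pmf is
  $\frac{\Gamma(x+m)}{\Gamma(x)\Gamma(m+1)} \phi^m (1+\phi)^{-(x+m)}$ — the
  only normalized reading, equal to `dnbinom(m, size = x, prob = 1/(1+phi))`.

`simulate_tvmt()` iterates the recursion exactly (one thinning draw, one
Poisson draw per step) with a burn-in, 500 steps by default, and an initial
count drawn from Poisson($\lambda$); stationarity and ergodicity make the
initialization asymptotically irrelevant, and the burn-in removes its
finite-sample footprint. A single seeded R RNG stream drives covariates,
thinning and innovations; a covariate path can be held fixed across
replications by passing a precomputed matrix instead of covariate
specifications.

## Estimation

Write $\theta = (\beta_1^\top, \beta_2^\top, \lambda)^\top$ and
$g(\theta, X_{t-1}, Z_t) = \phi_{i,t} X_{t-1} + \lambda$ for the one-step
conditional mean.

**Conditional least squares** (`fit_cls()`) minimizes
$Q(\theta) = \sum_t (X_t - g)^2$. The estimator is asymptotically normal
with sandwich covariance $V^{-1} W V^{-1}$, estimated by plugging analytic
derivatives of $g$ into
$\hat V = n^{-1}\sum \nabla g \nabla g^\top$ and
$\hat W = n^{-1}\sum U_t^2 \nabla g \nabla g^\top$.

**Conditional maximum likelihood** (`fit_cml()`) maximizes
$L(\theta) = \sum_t \log P(X_t \mid X_{t-1}, Z_t)$, conditioning on the
first observation. Standard errors come from the inverse negative Hessian
at the optimum (numerical, central differences). The likelihood and its
analytic score are evaluated in compiled code; each step's convolution is
accumulated in linear space (all terms lie in $[0,1]$) with table-driven
log-gamma values, and per-step probabilities are floored at $10^{-300}$ so
degenerate parameter corners stay finite during optimization.

Both fits use box-constrained multi-start L-BFGS-B. The box is
$\beta \in [-20, 20]$ per coordinate (wide enough to cover the kind of
near-boundary coefficient a real fit can produce) and
$\lambda \in [10^{-6}, 10\bar x]$. Starts are a moment-based point — zero
slopes, so both links sit at $\phi = 1/2$, and
$\lambda_0 = \overline{X_t} - \tfrac12 \overline{X_{t-1}}$ — plus a
configurable number of randomized perturbations (`tvmt_control()`,
default 2). The CML fit additionally starts from the CLS estimate, which
is cheap and almost always in the right basin. The Monte Carlo drivers trim
the randomized extra starts to one: across the replication studies the
moment/CLS starts converge to the same optimum as larger start sets, and
the saving compounds over thousands of fits. Thinning probabilities are
clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the likelihood so score terms
with $1/\phi$ or $1/(1-\phi)$ stay finite when a linear predictor
saturates the logistic link.

**Threshold search** (`fit_threshold()`): because $r$ is an integer the
criterion is not differentiable in it, so the estimator is a two-step scan.
Step 1 fits the model at every integer between the empirical 10th and 90th
quantiles of the counts (order-statistic quantiles, so candidates are
integers by construction) and scores each by $Q$ (CLS) or $L$ (CML);
Step 2 keeps the fit at the winning candidate. Ties go to the smallest
candidate, and the whole objective profile is returned so near-ties are
visible. Consecutive candidates are warm-started from their neighbor's
estimate. When either regime ends up holding less than 20% of the
transitions — the occupancy guideline the reference designs impose — the
fit proceeds with a warning.

## Hypothesis tests

* `test_piecewise()` — Wald statistic
  $T_n^{(1)} = \mathbf 1^\top(\hat\beta_1 - \hat\beta_2) /
  \sqrt{A \hat\Sigma A^\top / n}$ with $A = (\mathbf 1, -\mathbf 1)$
  applied to the coefficient block of the CLS sandwich covariance (the
  $\lambda$ coordinate is zero-padded; that is the only conformable
  reading). Asymptotically standard normal under
  $H_0: \beta_1 = \beta_2$. The default decision is one-sided
  ($T > z_{0.95} = 1.645$ at the 5% level), which matches the critical
  value and empirical sizes of the reference study; a two-sided option is
  available.
* `test_covariates_wald()` — $T_n^{(2)} = n \hat\theta^\top C^\top
  (C \hat\Sigma C^\top)^{-1} C \hat\theta$ with $C$ selecting the $2q$
  slope coefficients (again zero-padded in $\lambda$); asymptotically
  $\chi^2_{2q}$ under the null of no covariate effect.
* `test_covariates_lr()` — likelihood ratio
  $T_n^{(3)} = 2(\hat L - \hat{\tilde L})$ against the
  constant-coefficient MTTINAR(1) null fitted by `fit_mtt()`
  ($\alpha_i$ replacing the logistic links; the null is nested via
  $\beta_{i,0} = \operatorname{logit}\alpha_i$, slopes zero);
  asymptotically $\chi^2_{2q}$.

In test workflows where the generating process has no threshold (the
single-regime null designs), the fitted threshold is set to the
per-replication sample median — both regimes are then guaranteed occupancy
and the choice is configurable. Where the design has a true threshold it
is treated as known, as the reference analyses do.

## Diagnostics

`pearson_residuals()` standardizes one-step prediction errors by the
conditional standard deviation; under a correct model their mean tends to
0, their variance to 1, and their autocorrelations vanish. The regime-2
conditional variance uses the negative-binomial dispersion
$\phi_2(1+\phi_2)X_{t-1} + \lambda$ (the source expression repeats the
regime-1 indicator where the regime-2 indicator is clearly intended; the
package implements the corrected form). `model_rms()` is the root mean
square one-step error; `info_criteria()` applies the standard
$-2L + 2k$ / $-2L + k\log n$ penalties (stated explicitly because model
comparisons depend on them); `below_threshold_rate()` reports the fraction
of *lagged* counts at or below $r$ — the quantities that actually drive the
regimes.

## The simulation study harness

`sim_design()` reproduces the reference study designs exactly: A/B models
for estimator bias and MSE (identical parameters, opposite orientation
flag $R$), T1x/T2x single-regime time-varying INAR null models for the
piecewise test, T3x its alternatives, T4x constant-coefficient MTTINAR
nulls for the covariate tests, and T5x their alternatives. The covariate
processes are i.i.d. N(0,1), an AR(1) recursion
$Z_t = \pm 0.5 Z_{t-1} + \epsilon_t$ started at zero, a seasonal
sinusoid $\sin(2\pi t/12)$ plus N(0, 0.25) noise, and i.i.d. U(−10, 1)
draws. Covariates are regenerated independently in every replication. For
the T4x designs the generating process has no covariates at all; the
U(−10, 1) column the harness attaches is pure noise supplied to the fitted
model, which is exactly what a size calculation requires.

`mc_estimation()`, `mc_test()` and `mc_threshold()` drive the
replication loops and report Monte Carlo standard errors alongside every
bias, MSE and rate, so any comparison against a published table can use
explicit $3\,\mathrm{SE}$ bands. The package defaults run these studies at
500 replications (200 for the grid-search study, whose inner loop fits the
model at every candidate threshold) against the reference study's 10,000;
the Monte Carlo bands widen accordingly, roughly 4.5-fold. Replication
summaries are deterministic given the seed.

What the generator does *not* emulate is worth stating: real series bring
covariates that are neither stationary nor exogenous, innovation laws with
extra dispersion, and possible change points. Passing the simulation-based
checks shows the inference machinery is correct under the model's own
assumptions, not that the model fits any particular dataset; the
diagnostics above are the tool for that second question.

## Known limitations

* No higher-order lags, non-Poisson innovations, or finite-range variants.
* No standard error for the estimated threshold and no profile-likelihood
  set for it; the two-step estimator is reported as a point.
* CML standard errors near the $\lambda$ boundary rely on a numerical
  Hessian and are flagged (set to `NA`) when it is not positive definite.
* The piecewise Wald test is implemented as one-sided by default; under
  alternatives where $\mathbf 1^\top(\beta_1 - \beta_2) < 0$ the two-sided
  option should be used.
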
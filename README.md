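# tvmttinar

Threshold INAR(1) models for count time series whose autoregressive
strength varies with observable explanatory variables.

## The problem and the model

Count series (trade counts, surveillance case counts, event tallies) often
switch dynamics depending on their own level, while external conditions
modulate how strongly the past carries forward. `tvmttinar` implements a
first-order **t**ime-**v**arying **m**ixture-**t**hinning **t**hreshold
**INAR** process that captures both:

$$X_t = (\phi_{1,t} \circ X_{t-1})\,I_{1,t} +
        (\phi_{2,t} * X_{t-1})\,I_{2,t} + \epsilon_t,$$

where $\circ$ is binomial thinning, $*$ is negative-binomial thinning (an
over-dispersed survival mechanism), $\epsilon_t \sim$ Poisson($\lambda$),
and $I_{1,t}$ indicates whether the lagged count sits at or below an
integer threshold $r$ (an orientation flag $R \in \{0,1\}$ decides which
operator acts below the threshold). The thinning probabilities follow a
logistic link in covariates: $\operatorname{logit}\phi_{i,t} = Z_t^\top
\beta_i$.

The package provides:

* exact transition probabilities, conditional moments, and exact
  simulation (`transition_pmf()`, `cond_mean()`, `simulate_tvmt()`);
* conditional least squares and conditional maximum likelihood estimation
  with asymptotic covariances — CLS with the sandwich
  $\hat V^{-1}\hat W\hat V^{-1}$, CML with the inverse negative Hessian
  (`fit_cls()`, `fit_cml()`);
* a two-step grid search for the integer threshold over the empirical
  10th–90th quantile range (`fit_threshold()`);
* three tests: a Wald test of the piecewise structure
  $H_0: \beta_1 = \beta_2$ (`test_piecewise()`), and Wald and
  likelihood-ratio tests of the presence of explanatory variables against
  the constant-coefficient MTTINAR(1) null
  (`test_covariates_wald()`, `test_covariates_lr()`, `fit_mtt()`);
* diagnostics — Pearson residuals, RMS, AIC/BIC, below-threshold rate
  (`pearson_residuals()`, `diagnose()`);
* a seeded Monte Carlo harness reproducing the reference simulation
  designs (`sim_design()`, `mc_estimation()`, `mc_test()`,
  `mc_threshold()`).

Everything takes and returns tibbles; fitted objects support `tidy()`,
`glance()`, `residuals()` and `autoplot()`.

## A worked example

Simulate a two-regime series with one standard-normal covariate, estimate
the threshold and the parameters by CML, and test the structure:

```r
library(tvmttinar)

model <- tvmt_model(beta1 = c(0.1, 0.3), beta2 = c(-0.5, -0.6),
                    lambda = 5, r = 6, R = 0)
set.seed(1)
series <- simulate_tvmt(model, n = 1000,
                        covariates = list(cov_iid_normal()))

fit <- fit_threshold(series, R = 0, method = "cml")
fit
#> TVMTTINAR(1) fit (CML), r = 6, R = 0, n = 999
#>           estimate std.error
#> beta1_0  0.1832894 0.2344894
#> beta1_1  0.3164325 0.1249306
#> beta2_0 -0.3765271 0.1235835
#> beta2_1 -0.6626653 0.0623957
#> lambda   4.9059660 0.2698910
#> logLik = -2524.313
```

The grid search recovers the true threshold ($\hat r = 6$) and every
coefficient lands within two standard errors of its generating value.
The hypothesis tests confirm what was simulated — a genuine piecewise
structure and genuinely informative covariates:

```r
test_piecewise(fit_cls(series, r = fit$r))
#> statistic=6.61696 dist=standard normal (one-sided) critical=1.645 level=0.05 reject=TRUE
test_covariates_lr(series, r = fit$r)
#> statistic=170.504 dist=chi-square(2) critical=5.991 level=0.05 reject=TRUE

diagnose(fit)
#> # A tibble: 1 × 10
#>   method     r     R pearson_mean pearson_var   rms   aic   bic rate_below     n
#>   <chr>  <int> <int>        <dbl>       <dbl> <dbl> <dbl> <dbl>      <dbl> <int>
#> 1 CML        6     0      0.00381        1.02  3.19 5059. 5083.      0.296   999
```

Pearson residuals with mean ≈ 0 and variance ≈ 1 indicate a well-balanced
fit. Monte Carlo studies of any registered design run the same way:

```r
mc_test("T11", n = 1000, reps = 500, stat = "T1", seed = 1)
# empirical size of the piecewise Wald test under a single-regime null
```

A thin command-line wrapper (`inst/cli/tvmttinar`) exposes
`simulate | fit | test | study` subcommands over the same functions.

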
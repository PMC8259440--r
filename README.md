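# noncollapse

Separating confounding bias from the noncollapsibility effect in logistic
regression.

## The problem

In observational studies with a binary outcome, researchers often judge
confounding by the *change-in-estimate* criterion: compare the exposure
coefficient between a univariable model,
`logit Pr(Y=1|X) = i1 + β1·X`, and a multivariable model,
`logit Pr(Y=1|X,C) = i2 + β1'·X + β2'·C1 + … + βk+1'·Ck`, and call the
covariates confounders when the coefficient moves by more than 10%. In
logistic regression this comparison is misleading: the odds ratio is
**noncollapsible**. The latent residual variance of a logistic model is
fixed at π²/3 ≈ 3.29, so adding outcome-associated covariates inflates the
total latent variance and rescales the exposure coefficient even when no
confounding exists.

The remedy implemented here compares three estimates:

* `β1` — unadjusted (univariable);
* `β1'` — conditional adjusted (multivariable);
* `β1*` — marginal adjusted, from an inverse-probability-weighted (IPW)
  logistic regression of `Y` on `X` alone, with weights from the propensity
  model `logit Pr(X=1|C) = i3 + λ1·C1 + … + λk·Ck` (stabilized by default:
  `p/PS` for exposed, `(1−p)/(1−PS)` for unexposed subjects).

Then

```
confounding bias        = β1  − β1*
noncollapsibility effect = β1* − β1'
change in estimate      = β1' − β1   (= −(bias + noncollapsibility), exactly)
```

The package provides the three estimators (plus G-computation as a second
marginal estimator), the decomposition with percentile-bootstrap confidence
intervals, exact large-sample limits of all three estimands via
Gauss–Hermite quadrature, a synthetic-cohort generator, and a factorial
Monte Carlo study runner. It is aimed at epidemiologists and
methodologists who want to quantify how much of an observed coefficient
change is real confounding.

## Worked example

```r
library(noncollapse)

params <- generation_params(n_subjects = 1000, beta_xy = 0.92,
                            lambda_cx = 0.92, beta_cy = 0.92, seed = 42)
ch  <- generate_cohort(params)
tri <- estimate_effects(ch)
tri
#> Exposure effect estimates (log odds ratios):
#>   beta1  (unadjusted, univariable)       2.1407
#>   beta1' (conditional, multivariable)    1.0858
#>   beta1* (marginal, IPW)                 0.7937

decompose(tri)
#> Decomposition of the change in estimate (log-odds scale):
#>   change in estimate    (beta1' - beta1)   -1.0549
#>   confounding bias      (beta1 - beta1*)    1.3470
#>   noncollapsibility     (beta1* - beta1')  -0.2921
#>   percent change 49.3%; percent confounding 62.9%
#>   ...

theoretical_effects(params)
#> Large-sample limits (log odds ratios):
#>   unadjusted  (beta1 limit)     2.0133
#>   conditional (beta1' limit)    0.9200
#>   marginal    (beta1* limit)    0.6349
#>   confounding bias limit        1.3784
#>   noncollapsibility limit      -0.2851
#>   latent residual variance      3.2899 (pi^2/3, displayed as 3.29)
```

The unadjusted estimate (2.14) is badly confounded; the conditional (1.09)
and marginal (0.79) adjusted estimates are both valid but differ by the
noncollapsibility effect. The change in estimate (−1.05) is *not* the
confounding bias (1.35): the two components partly cancel. The quadrature
limits confirm each estimate is near its large-sample target.

Bootstrap uncertainty, user data, and the factorial experiment:

```r
bootstrap_decomposition(ch, n_resamples = 1000, seed = 1)
ch2 <- read_cohort("cohort.csv")          # columns y, x, c1..ck
run_study(study_grid(repetitions = 100))  # 1372-condition factorial study
```

A thin command-line wrapper with `simulate`, `decompose`, `oracle` and
`study` subcommands is installed at `inst/cli/noncollapse.R`.

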
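# metacover

Random-effects meta-analysis with honest interval uncertainty: REML
estimation, six confidence/prediction-interval constructions, and a
Monte-Carlo engine for measuring how well each interval actually covers.

## The problem

A random-effects meta-analysis pools $k$ study estimates
$\hat\theta_i$ (each with within-study variance $\hat\sigma_i^2$) under

$$\hat\theta_i \sim N(\theta_i, \hat\sigma_i^2), \qquad
  \theta_i \sim N(\theta, \tau^2),$$

and reports a confidence interval for the mean effect $\theta$ and,
increasingly, a prediction interval for the effect in a new population.
The conventional interval
$\hat\theta \pm z_{\alpha/2}\,\hat\sigma_\theta$ treats the REML estimate
$\hat\tau^2$ as known and is too narrow when studies are few. This
package implements, behind one interface, the main small-sample
corrections a meta-analyst will encounter:

| id  | idea |
|-----|------|
| `N`   | conventional normal-quantile interval |
| `HK`  | Hartung–Knapp: variance rescaled by the weighted residual mean square $q$, $t_{k-1}$ reference |
| `HK2` | HK with the factor floored at 1, so never narrower than `N` |
| `SJ`  | Sidik–Jonkman robust (sandwich) variance, $t_{k-1}$ |
| `SJ2` | bias-corrected SJ (residuals inflated by $(1-h_i)^{-1}$) |
| `KR`  | Kenward–Roger: expected-information-adjusted variance with fractional df $\nu$ |

Prediction intervals follow the Higgins construction
$\hat\theta \pm t_{k-2;\alpha/2}\sqrt{\hat\tau^2 + V}$ with each method's
$V$ substituted (and $t_{\nu-1}$ for `KR`).

Because none of these is uniformly reliable, the package also ships the
measurement instrument: a seeded generator of synthetic meta-analyses
(normal random effects, $\chi^2$-distributed within-study variance
estimates, configurable study-size imbalance) and a coverage engine that
tabulates, over thousands of replications, how often each of the twelve
interval types contains its target. It is aimed at biostatisticians
evaluating interval methods and at meta-analysts who want to know when
their prediction interval can be trusted.

## Worked example

Seven randomised trials of anti-hypertensive treatment (difference in
diastolic blood pressure, mmHg, treatment minus control) are bundled:

```r
library(metacover)
post <- dbp_meta("post")
fit_reml(post)
#> Random-effects meta-analysis (REML), k = 7 studies
#>   pooled effect theta  = -8.921  (se 0.6928 )
#>   between-study tau^2  = 1.729
#>   I^2                  = 69.4%
meta_intervals(post)
#>  method estimate ci_low ci_high pi_low pi_high tau2   i2 df_ci df_pi
#>       N    -8.92  -10.3   -7.56  -12.7   -5.10 1.73 69.4   Inf  5.00
#>      HK    -8.92  -10.7   -7.16  -12.8   -5.07 1.73 69.4  6.00  5.00
#>     HK2    -8.92  -10.7   -7.16  -12.8   -5.07 1.73 69.4  6.00  5.00
#>      SJ    -8.92  -10.4   -7.44  -12.6   -5.20 1.73 69.4  6.00  5.00
#>     SJ2    -8.92  -10.6   -7.26  -12.7   -5.12 1.73 69.4  6.00  5.00
#>      KR    -8.92  -11.3   -6.58  -16.0   -1.86 1.73 69.4  2.82  1.82
```

Treatment lowers blood pressure by about 9 mmHg on average, with
substantial heterogeneity ($I^2 = 69\%$, $\hat\tau^2 = 1.73$): every
method's 95% CI excludes zero, but the conventional interval is visibly
the narrowest, and the prediction interval for a new population is far
wider than any CI. The Kenward–Roger row illustrates its fractional
degrees of freedom ($\nu = 2.82$).

Coverage of a difficult corner — three balanced studies with large
heterogeneity — shows why the adjustments exist:

```r
run_scenario(meta_scenario(k = 3, nu_ratio = 10, seed = 1), n_reps = 10000)
```

gives 95% CI coverage of about 82% for `N` against about 95% for `HK`.
Grids of scenarios are driven by a YAML config
(`system.file("extdata", "default_grid.yaml", package = "metacover")`)
through `run_grid()` / `write_coverage_report()`, or from the shell via
the bundled CLI:

```sh
inst/cli/metacover analyze inst/extdata/dbp_post.csv
inst/cli/metacover simulate --config inst/extdata/default_grid.yaml --outdir reports/
```

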
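---
title: "Confidence and prediction intervals for random-effects meta-analysis: methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence and prediction intervals for random-effects meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacover)
```

## The model

A random-effects meta-analysis combines $k$ study-level estimates
$\hat\theta_i$ of a treatment effect, each with a within-study sampling
variance $\hat\sigma_i^2$ that the model treats as known. Because the
studies draw on different populations and protocols, each is allowed its
own true effect $\theta_i$, varying around an overall mean:

$$\hat\theta_i \sim N(\theta_i,\, \hat\sigma_i^2), \qquad
  \theta_i \sim N(\theta,\, \tau^2).$$

The two estimands of interest are the mean effect $\theta$ (summarised by a
confidence interval) and the effect to be expected in a *new* study or
population (summarised by a prediction interval). The between-study
variance $\tau^2$ is estimated by restricted maximum likelihood (REML),
which accounts for the simultaneous estimation of $\theta$; `fit_reml()`
maximises the profile restricted log-likelihood

$$\ell_R(\tau^2) = -\tfrac12\Big[\textstyle\sum_i \log(\hat\sigma_i^2+\tau^2)
  + \log\sum_i w_i + \sum_i w_i(\hat\theta_i-\hat\theta)^2\Big],
  \qquad w_i = \frac{1}{\hat\sigma_i^2+\tau^2},$$

by the standard fixed-point iteration
$\tau^2 \leftarrow \max\{0,\ \sum_i w_i^2[(\hat\theta_i-\hat\theta)^2 -
\hat\sigma_i^2]/\sum_i w_i^2 + 1/\sum_i w_i\}$, started from the
DerSimonian–Laird moment estimate. The iteration stops when successive
$\tau^2$ values change by less than `tol` ($10^{-10}$ by default, on the
squared-outcome scale) or after `max_iter` (200) iterations, in which case
the last iterate is returned with `converged = FALSE` rather than an
error — a deliberate choice so that large simulation runs can count and
exclude failures instead of halting. `restricted_log_likelihood()` is
exported so that the optimiser can always be checked against a dense grid
search, which is exactly what the test suite does.

Heterogeneity is additionally summarised by Cochran's
$Q = \sum_i \hat\sigma_i^{-2}(\hat\theta_i - \bar\theta_{FE})^2$ under
fixed-effect weights and by $I^2 = 100\,\max\{0, (Q-(k-1))/Q\}$, the
percentage of total variation attributable to between-study heterogeneity.
Several $I^2$-like definitions circulate; the $Q$-based one above is used
consistently here, including for the per-replication average that the
coverage engine reports.

## Six interval constructions

All six methods centre the interval on the REML pooled estimate
$\hat\theta = \sum_i w_i \hat\theta_i / \sum_i w_i$ and differ in the
variance $V$ attributed to it and in the reference distribution:

| id | variance of $\hat\theta$ | CI reference |
|------|----------------------------------------------|--------------|
| N | $\hat\sigma_\theta^2 = 1/\sum_i w_i$ | $z$ |
| HK | $q\,\hat\sigma_\theta^2$, $\;q = \frac{1}{k-1}\sum_i w_i(\hat\theta_i-\hat\theta)^2$ | $t_{k-1}$ |
| HK2 | $\max\{1, q\}\,\hat\sigma_\theta^2$ | $t_{k-1}$ |
| SJ | $\sum_i w_i^2(\hat\theta_i-\hat\theta)^2 / (\sum_i w_i)^2$ | $t_{k-1}$ |
| SJ2 | $\sum_i w_i^2(1-h_i)^{-1}(\hat\theta_i-\hat\theta)^2 / (\sum_i w_i)^2$ | $t_{k-1}$ |
| KR | $\mathrm{Var}_{KR}$ below | $t_{\nu}$ |

The conventional interval (N) ignores the uncertainty in $\hat\tau^2$ and
is known to undercover when $k$ is small and heterogeneity is non-trivial.
The Hartung–Knapp rescaling (HK) fixes this in most settings but can
*shrink* the interval when $q < 1$; HK2 floors the factor at one so that
the adjusted interval is never shorter than the conventional one. The
Sidik–Jonkman variance (SJ) is a sandwich estimator robust to
misspecified weights; its bias-corrected form (SJ2) inflates each squared
residual by $(1-h_i)^{-1}$ with $h_i$ the hat value of study $i$ in the
weighted least-squares fit of a common mean.

**Leverage choice for SJ2.** With a single intercept and weights $w_i$,
the WLS hat value is $h_i = w_i / \sum_j w_j$, and that is what
`variance_sj2()` uses. Published presentations of this estimator sometimes
write $h_i$ through an auxiliary scale $\lambda_i$ whose definition is
easy to typeset ambiguously; identifying $\lambda_i^2 = 1/w_i$ collapses
any such form to the hat value above, which is also the quantity in the
original derivation of the bias correction. Two structural facts follow
and are enforced by tests: $\mathrm{Var}_{SJ2} \ge \mathrm{Var}_{SJ}$
always, with equality factor $k/(k-1)$ under equal weights. A consequence
worth knowing: any published SJ2 interval that is *narrower* than its SJ
companion cannot have been produced by this (or any) leverage correction.

**Kenward–Roger.** The KR approach inflates the variance for the
uncertainty in $\hat\tau^2$ using the expected information of the REML
profile and pairs it with a matching, typically fractional, degrees of
freedom. With weight moments $w_{j\bullet} = \sum_i w_i^j$:

$$I_E = \frac{w_{2\bullet}}{2} - \frac{w_{3\bullet}}{w_{1\bullet}}
      + \frac12\Big(\frac{w_{2\bullet}}{w_{1\bullet}}\Big)^2,\qquad
\mathrm{Var}_{KR} = \frac{1}{w_{1\bullet}}
      + \frac{2\,(w_{3\bullet} - w_{2\bullet}^2/w_{1\bullet})}
             {w_{1\bullet}^2\, I_E},\qquad
\nu = \frac{2\, I_E}{\mathrm{Var}_{KR}^2\, w_{2\bullet}^2}.$$

Under equal weights $w_{3\bullet} - w_{2\bullet}^2/w_{1\bullet} = 0$, so
$\mathrm{Var}_{KR}$ reduces to the conventional variance and $\nu$ to
$k-1$ — a closed form the tests exploit. With a mixture of large and small
studies $\nu$ can fall below 2, which makes the KR intervals extremely
wide.

**Prediction intervals.** The interval for the effect in a new study
combines the heterogeneity with the uncertainty in the mean
(the Higgins construction):
$\hat\theta \pm t_{k-2;\alpha/2}\sqrt{\hat\tau^2 + V}$, where $V$ is the
method's variance of $\hat\theta$ (so the HK2 floor carries into the HK2
prediction interval). For KR the natural analogue replaces $k-2$ by
$\nu - 1$. The $k-2$ rule needs $k \ge 3$, and the KR rule needs
$\nu > 1$; `prediction_interval()` refuses otherwise with an explanation,
and `meta_intervals()` converts the refusal into `NA` columns so that the
remaining methods still report.

## Numerical sensitivity of small fractional degrees of freedom

When $\nu - 1$ is a small fraction (around 0.5, as happens for a
homogeneous meta-analysis with strongly unbalanced study sizes), the
$t$-quantile is enormous and *hyper-sensitive*: moving $\nu$ from 1.55 to
1.54 moves a 97.5% quantile by more than 10%. Inputs recorded at two
decimals are then simply not precise enough to pin down the KR prediction
interval — re-deriving the bundled pre-treatment example's standard errors
from their printed confidence intervals instead of their printed SE column
moves the KR prediction bound from about $\pm 36$ to about $\pm 46$. The
package therefore reports such intervals exactly as computed, and users
comparing against published KR intervals should expect agreement in $\nu$
to a percent or two but not agreement of extreme quantiles to printed
decimals. The other five methods do not share this amplification.

## What the generator emulates

`simulate_meta()` reproduces a standard simulation design for this model:

* true study effects $\theta_i \sim N(\theta, \tau^2)$;
* estimated within-study variances
  $\hat\sigma_i^2 = \sigma_i^2\, X_i/(n-1)$ with
  $X_i \sim \chi^2_{n-1}$, centred on the true $\sigma_i^2$, so that the
  analyst's variances are themselves noisy — the realistic situation the
  small-sample adjustments are meant to address;
* effect estimates $\hat\theta_i \sim N(\theta_i, \sigma_i^2)$ drawn with
  the **true** variance (the estimation error of $\hat\sigma_i^2$ enters
  only through the fitted model, not the data generation);
* one new-study effect from $N(\theta, \tau^2)$ per replication, the
  target of prediction-interval coverage.

Defaults are $\theta = 1$, $\sigma^2 = 0.1$, $n = 30$, and heterogeneity
expressed through $\nu = \tau^2/\sigma^2 \in \{10, 1, 0.5, 0.1\}$
(i.e. $\tau^2 \in \{1, 0.1, 0.05, 0.01\}$), with
$k \in \{3, 5, 7, 10, 100\}$ in the bundled default grid. Study-size
imbalance is introduced through the true variances only: `one_large`
gives study 1 a tenfold smaller variance, `one_small` a tenfold larger
one, and `mixture` alternates the two (study 1 large, study 2 small, ...).
The alternating composition is this package's own convention — published
"mixture" scenarios rarely state theirs, so mixture cells should be
compared across packages only qualitatively. Nothing is rescaled to
compensate, so the unbalanced patterns also change the effective
heterogeneity, and $\nu$ or $I^2$ must be interpreted with care there.

The generator deliberately does **not** emulate several features of real
meta-analyses: no correlation between effect size and standard error (as
arises with binary outcomes), no non-normal random effects, no
publication bias, and no outcome-specific constraints. Passing coverage
tests therefore demonstrate calibration *under the model*, not robustness
to these violations.

## The coverage engine

`run_scenario()` repeats simulate–fit–construct `n_reps` times and counts,
per method, how often the confidence interval contains $\theta$ and the
prediction interval contains the new-study draw (closed intervals; the
endpoint convention is immaterial for continuous draws but fixed for
determinism). Replications whose REML iteration does not converge are
counted in `n_failed` and excluded from all denominators; replications
where only the KR prediction interval is undefined are excluded from that
cell alone (`n_used` records effective counts). The per-replication
$Q$-based $I^2$ is averaged into `mean_i2`, and `mc_error()` gives the
binomial Monte-Carlo standard error — at the 95% level with $10^4$
replications about 0.22 points, so observed coverage outside
$[94.6, 95.4]$ is a real departure.

Reproducibility uses L'Ecuyer-CMRG substreams: replication $r$ starts from
the $r$-th `parallel::nextRNGStream()` state derived from the seed, so a
scenario's result is bit-identical no matter how the replications are
chunked, and the caller's RNG state is restored afterwards. `run_grid()`
derives each scenario's seed deterministically from the grid seed and the
scenario's position.

Problem sizes: the package default is 10 000 replications per cell,
matching common practice for coverage studies of this model; the bundled
test suite runs its calibration checks at 2 000 replications with
correspondingly widened (±1.5 point) bands, a size chosen to keep the
suite comfortably interactive while leaving the Monte-Carlo error (about
0.5–0.9 points per cell) well inside those bands.

## Worked example

The bundled fixture is a meta-analysis of seven randomised trials of
anti-hypertensive treatment, recorded at the two-decimal precision of the
published report. Post-treatment, heterogeneity is substantial and the
conventional interval is visibly narrower than the adjusted ones:

```{r}
post <- dbp_meta("post")
fit_reml(post)
meta_intervals(post)
```

Pre-treatment (the baseline difference, where homogeneity is expected),
$\hat\tau^2$ is near zero and the KR degrees of freedom collapse to
$\nu \approx 1.55$, producing the erratic KR prediction interval discussed
above:

```{r}
meta_intervals(dbp_meta("pre"))
```

## Known limitations

* REML is the only heterogeneity estimator offered (DerSimonian–Laird
  appears solely as a starting value); no Paule–Mandel, ML, or
  profile-likelihood intervals for $\tau^2$.
* No effect-size computation from raw study data (2×2 tables, means and
  SDs): inputs are estimate-plus-SE pairs.
* The $I^2$ interval sometimes reported alongside the point value has no
  single standard construction and is not computed.
* Prediction-interval coverage below nominal in low-heterogeneity or
  unbalanced settings is a property of these frequentist constructions,
  not a defect of the implementation; the coverage engine exists precisely
  to quantify it.
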
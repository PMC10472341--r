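---
title: "Validating small-area prevalence estimates against an external survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating small-area prevalence estimates against an external survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saeprev)
```

## The estimation problem

We want the prevalence of a three-category outcome — smoker (S), ex-smoker
(ExS), never smoker (NS) — in small areas defined by crossing region, sex
and five age bands (15–34, 35–54, 55–64, 65–74, ≥75). A national survey
covers all areas but thinly; a regional survey covers a subset of areas
with much larger samples (about six respondents per area for every national
one, in the default scenario). The package estimates each area two ways and
quantifies whether they agree:

1. **Direct (design-based)**: the Hájek ratio estimator applied to the
   representative regional survey, with Taylor-linearized variance. It uses
   only the area's own respondents, so it is approximately design-unbiased
   but noisy — and simply does not exist for an empty cell.
2. **Model-based (SAE)**: a mixed multinomial logit fitted to the national
   survey's area-aggregated counts, which borrows strength across areas.

## The model

For area $d$ and non-reference categories $k = 1$ (S), $2$ (ExS):

$$\eta_{dk} = x_{dk}'\beta_k + u_{dk}, \qquad u_{dk} \sim N(0, \phi_k),$$
$$p_{dk} = \frac{e^{\eta_{dk}}}{1 + e^{\eta_{d1}} + e^{\eta_{d2}}}, \qquad
  p_{d3} = 1 - p_{d1} - p_{d2}.$$

The response is the vector of per-area counts $(y_{d1}, y_{d2}, y_{d3})$,
multinomial with the area's sample size. Counts enter unweighted: the model
describes the sampled individuals, and the covariates plus random effects
absorb area-level structure. The random effects are independent across
areas and categories with category-specific variances $\phi_k$ — the single
covariance structure the package supports. Assumptions worth keeping in
mind: covariates measured without error, no spatial or temporal
correlation, and a correctly specified logit scale.

### Fitting

The marginal likelihood integrates the $u_{dk}$ out; it factorizes over
areas into two-dimensional integrals, each approximated by Laplace's method
around the mode of the penalized per-area log-likelihood (a strictly
concave 2-D problem solved by damped Newton, vectorized across areas). The
outer optimization over $(\beta_1, \beta_2, \log\phi_1, \log\phi_2)$ uses
`nlminb` with a relative objective tolerance of `1e-6` (tightenable via
`rel_tol`) and at most 200 iterations; the evaluated objective path is kept
on the fit object for monitoring. Starting values are a fixed-effects
multinomial logit (own Newton solver) and $\phi_k = 0.05$. The log
parameterization keeps variances nonnegative; an estimate below $10^{-8}$
is reported as on the boundary, where the predicted effects are exactly
zero and the model coincides with the fixed-effects multinomial logit.
`fit_sae(..., random_effects = FALSE)` fits that degenerate submodel
directly. On finite data generated with $\phi = 0$ the free
$\hat\phi_k$ typically lands a little above zero rather than exactly on the
boundary — maximum likelihood for a boundary parameter behaves this way —
which is why the collapse property is asserted both ways in the tests.

### Prediction and precision

Areas with sample use the full predictor $x_{dk}'\hat\beta_k + \hat
u_{dk}$; areas with zero sample have no information to estimate a random
effect, so their prediction uses only the synthetic part
$x_{dk}'\hat\beta_k$ (automatic in `predict_prevalence(mode = "auto")`).
Precision is a parametric bootstrap (default $B = 200$): draw new random
effects and counts from the fitted model, refit (warm-started at the
estimates), and accumulate squared prediction errors into per-cell MSEs;
$CV = 100\sqrt{MSE}/\hat p$. Replicate refits that fail are dropped and
counted, with an error if more than 20% fail. The bootstrap evaluates MSE
at the estimated parameters, so it inherits their sampling error; the test
suite checks it stays within a factor of two of the true Monte-Carlo MSE
for at least 90% of cells in a 30-area scenario.

## The validation protocol

Two aspects are compared, concordance and precision.

**Concordance.** Per category, the one-way random-effects, single-measure,
absolute-agreement ICC over the $D$ areas shared by both methods:
$WMS = \sum_d\sum_m (p_{dm}-\bar p_{d\cdot})^2/D$,
$BMS = 2\sum_d (\bar p_{d\cdot}-\bar p_{\cdot\cdot})^2/(D-1)$,
$ICC = (BMS - WMS)/(BMS + WMS)$, deemed acceptable at $\ge 0.60$. The
factor 2 in $BMS$ is the number of methods, as the standard one-way ANOVA
mean square requires. The 95% CI uses the exact F pivots: with $F_l, F_u$
the 97.5th percentiles of $F_{D-1,D}$ and $F_{D,D-1}$ and
$F_L = BMS/(WMS\,F_l)$, $F_U = BMS\,F_u/WMS$, the interval is
$((F_L-1)/(F_L+1),\; (F_U-1)/(F_U+1))$. The $+1$ in the denominators is the
$m - 1 = 1$ term of the standard two-method interval; we verified by
simulation (2000 replicates, $D = 10$, true ICC 0.8) that this form attains
~94% empirical coverage whereas dropping the $+1$ collapses coverage to
~86%, so the package uses the calibrated form. Per-area differences are
oriented model minus direct, with Wald 95% CIs using the summed variances
of the two independent surveys; the 1.96 multiplier is fixed because the
protocol is defined at the 95% level. Zero-inclusion percentages are
truncated (not rounded) to one decimal, the printing convention of the
surveillance reports this protocol follows.

**Precision.** A CV strictly below 30% is acceptable (the National Center
for Health Statistics reliability rule). `cv_screen()` also produces
median/IQR/range summaries and supports explicitly logged exclusion of
individual cells — the intended use is a near-empty cell whose enormous
direct-estimator CV would distort a summary, never silent deletion.

Pearson correlation is deliberately not offered as a validation mode: a
method that is systematically offset from the reference can correlate
perfectly while disagreeing everywhere, which is exactly what an
absolute-agreement index must detect.

## What the synthetic generator emulates — and what it does not

`generate_area_frame()` draws, per area, a lognormal population size, an
intercept plus two standardized continuous covariates per category
(stand-ins for the administrative smoking-related auxiliaries a real
analysis would use), random effects, and true prevalences through the
inverse link. `generate_survey()` draws multinomial statuses and attaches
weights: equal-allocation base `population/n` times lognormal noise with
unit mean and log-sd `weight_dispersion` (default 0.3), keeping weights
positive and their interpretation simple.

Defaults mirror the validation geometry the package is built around:
18 regions × 2 sexes × 5 age bands = 180 areas; ~130 national respondents
per area against ~780 regional (ratio 6, matching the reported 5.9);
intercepts chosen so average prevalences sit near 22% S / 25% ExS / 53% NS;
$\phi_k = 0.1$, a moderate area heterogeneity on the logit scale (the
variance of the area effects is a modelling assumption — survey reports do
not print it); and one deliberately empty national cell so the synthetic
prediction path is always exercised. Age bands are labelled 15–34 upward;
some survey documentation uses 16–34 for the youngest band, a discrepancy
the generic labels sidestep.

The generator is single-stage stratified sampling with noisy weights. It
does **not** emulate multi-stage clustering, nonresponse, calibration or
post-stratification — so passing tests show the estimators and protocol are
correct under the assumed design, not that the single-stage Taylor variance
captures a real survey's design effects. That is also why the variance
formula deliberately ignores stratum/PSU structure.

## Numerical choices and edge cases

- Inverse-link evaluations subtract the running maximum, so extreme linear
  predictors cannot overflow; probabilities sum to 1 to `1e-12`.
- Direct estimation: an empty area yields an explicit "no sample" record,
  not a zero; variance needs $n \ge 2$; a zero prevalence has SE 0 and an
  undefined CV, flagged rather than infinite.
- ICC needs at least 3 shared areas; prevalences outside $[0,1]$ are
  rejected; exact between-method agreement gives a degenerate CI reported
  as $(-1, 1)$ with a flag ($-1$ being the attainable lower bound of the
  two-method ICC).
- Validation excludes area × category cells lacking either estimate,
  pairwise per category, and logs them.
- Ties at the CV threshold: acceptability is the strict inequality
  $CV < 30$.

## Problem sizes used by the test suite

The statistical checks run at sizes chosen to make their Monte-Carlo error
small relative to the asserted tolerances while keeping the default suite
quick: 5000 areas for the generator's variance check; 50 replicates of a
60-area, 300-per-area recovery study; 2000 replicates for each coverage
check; a 30-area scenario with 200 outer replicates and $B = 100$ for
bootstrap-MSE calibration; and the full 180-area default scenario with
$B = 200$ end to end. Under reseeding of the default scenario the
qualitative findings are stable, though an occasional cell's model CV can
brush the 30% threshold (e.g. max CV ≈ 33% in one of ten reseeded runs we
examined); the ICCs stay far above 0.60.

## Known limitations

- Laplace approximation error is not corrected; for very small per-area
  counts adaptive quadrature would be more accurate.
- The bootstrap MSE ignores parameter-estimation uncertainty beyond what
  refitting captures, and is evaluated at $\hat\theta$ rather than the
  truth.
- Unweighted aggregation into the model counts assumes the within-area
  sampling is noninformative for status given the covariates.
- No model selection: the covariate set is taken as given.
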
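---
title: "Correcting for measurement error in a dietary confounder: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting for measurement error in a dietary confounder: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Serum concentrations of per- and polyfluoroalkyl substances (PFAS) such as
PFOA, PFOS, and PFNA are repeatedly found to be positively associated with
serum total cholesterol, even at background exposure levels. Dietary fiber
is a candidate confounder of that association: soluble fiber acts as a
bile-acid sequestrant, which both lowers serum cholesterol and increases
fecal excretion of PFAS. If fiber intake suppresses both quantities, an
unadjusted regression of cholesterol on PFAS is biased upward.

The catch is that habitual fiber intake is never observed. Survey data
provide two 24-hour dietary recalls per person, and day-to-day variation in
what people eat makes each recall a noisy measurement of long-term intake.
Adjusting for a noisily measured confounder removes only part of the
confounding — the residual-confounding problem — so a naive "adjust for the
2-day mean" analysis can understate how much of the PFAS–cholesterol
association fiber explains. `pfasfiber` implements both the naive analysis
and a Bayesian latent-variable correction, so the two can be compared on
the same data.

## The model

For subject $i$, let $Y_i$ be ln(serum total cholesterol, mg/dL), $X_i$ one
serum PFAS analyte (ng/mL, untransformed), $C_i$ the encoded secondary
covariates, and $F_i$ the latent long-term fiber intake on the transformed
scale described below. The generative model has three Gaussian parts:

$$Y_i \mid X_i, F_i, C_i \sim \mathrm N(\beta_0 + \beta_X X_i + \beta_F F_i
  + \beta_c^\top C_i,\ \sigma^2)$$
$$F_i \mid X_i, C_i \sim \mathrm N(\gamma_0 + \gamma_X X_i
  + \gamma_c^\top C_i,\ \omega^2)$$
$$F^*_{ij} \mid F_i \sim \mathrm N(F_i,\ \tau^2), \qquad j = 1, 2$$

The replicate model encodes three assumptions: the two recall days are
conditionally independent given the truth ("pure replicates"), the error is
nondifferential (independent of $Y$, $X$, $C$ given $F$), and the error is
unbiased (no systematic over- or under-reporting). Under them, the latent
$F_i$ integrates out in closed form and the observables
$(F^*_{i1}, F^*_{i2}, Y_i)$ are trivariate normal with

$$\mathrm{Var}(F^*_{ij}) = \omega^2 + \tau^2, \quad
  \mathrm{Cov}(F^*_{i1}, F^*_{i2}) = \omega^2, \quad
  \mathrm{Cov}(F^*_{ij}, Y_i) = \beta_F\,\omega^2, \quad
  \mathrm{Var}(Y_i) = \sigma^2 + \beta_F^2\,\omega^2.$$

`marginal_moments()` and `marginal_loglik()` implement this marginal
exactly (one Cholesky factorization of the shared 3×3 covariance per
parameter value), and `marginal_mle()` maximizes it numerically with the
variances on the log scale. The marginal is the package's independent
oracle: it validates the MCMC fitter without sharing any code with it, and
it is itself validated in the test suite against per-subject numerical
quadrature of the explicit latent-$F$ integral.

### Attenuation algebra

With $k$ replicates averaged, the reliability of the mean is
$\lambda = \omega^2 / (\omega^2 + \tau^2/k)$. Large-sample theory for the
naive regression that substitutes $\bar F^*_i$ for $F_i$ gives a fiber
slope of $\lambda\beta_F$ and a PFAS slope of
$\beta_X + \gamma_X \beta_F (1 - \lambda)$ — the second term is the
residual confounding that survives naive adjustment.
`attenuation_factor()` and `expected_naive_bias()` compute these closed
forms, and the test harness verifies that OLS on generated data converges
to them.

## The data pipeline

`read_analytic_csv()` reads a one-row-per-subject CSV (optionally through a
column-name dictionary); `sum_isomers()` totals the linear and branched
PFOA/PFOS isomers for the survey cycles that assayed them separately;
`impute_lod()` applies the LOD/√2 convention for values below the
detection limit (real analytic files arrive pre-imputed; the synthetic
generator uses it).

The fiber variable is built per recall day: regress the day's fiber (g/d)
on the day's energy (kcal/d) over the whole sample and keep the residual
(the residual method of energy adjustment, which isolates diet composition
from quantity), add a 40 g/d shift so the argument of the log is positive,
and take the natural log. The two transformed days are the replicates
$F^*_{i1}, F^*_{i2}$; their average is the observed-fiber regressor of the
OLS analysis. Day-specific adjustment regressions (rather than one pooled
fit) are used because the day-level intakes are the measured quantities;
averaging the transformed values (rather than transforming the averaged
raw intakes) makes the OLS fiber variable the mean of exactly the
replicates the latent-variable model uses, keeping the two analyses
comparable. The shift-log transform refuses arguments ≤ 0: such rows are
flagged for exclusion, never clipped.

The exclusion cascade runs once: complete-case filtering, removal of users
of cholesterol-lowering medication, then an outlier screen that drops
subjects whose ln-transformed shifted fiber or ln(cholesterol) lies more
than 2.57 standard deviations (the 99th-percentile band, used exactly as
2.57) from the mean of the post-medication sample. The screen uses
ln(cholesterol) together with *both* fiber variables so that the
fiber-free, total-fiber, and soluble-fiber models share a single sample
size. Re-running the screen on the retained sample would remove a few more
subjects (the z statistics shift); the pipeline deliberately applies the
rule exactly once, and a test documents that the second pass would remove
under 1%.

Covariate encoding: race/ethnicity (5 levels) and sex are reference-coded
indicators (reference levels configurable; default is the most frequent
level, and coefficients for these nuisance terms change interpretation but
not the PFAS or fiber coefficients); smoking is a single ordinal numeric
column (codes 0–3); the survey wave enters as a centered linear term plus
its square; energy (two-day mean), saturated fat, dietary cholesterol,
age, and the income-to-poverty ratio are mean-centered continuous columns
(income-to-poverty is kept continuous). Body mass index is excluded from
the default covariate set, matching the covariate list of the fitted
models; `include_bmi = TRUE` adds it when a `bmi` column exists.

## OLS reference analysis and the confounding criterion

`fit_ols()` regresses ln(cholesterol) on the analyte, optionally the
averaged fiber variable, and all covariates, with conventional standard
errors. `assess_confounding()` applies the change-in-estimate criterion:
confounding is flagged when adding fiber moves the PFAS coefficient by at
least 10%. The AIC uses the full Gaussian log-likelihood with the variance
counted as a parameter and constants retained, so `stats::AIC` on the
equivalent `lm` fit reproduces it exactly and differences are
comparison-safe; `quadratic_sensitivity()` uses it to compare the linear
model against one with an added squared (centered) PFAS term. Display
scaling — PFAS coefficients × 10³, fiber × 10² — lives only in
`render_table1()`; every computation uses raw scales.

## Bayesian fitting

All three model parts are Gaussian and the priors are conditionally
conjugate, so `fit_bayes()` samples the joint posterior of the parameters
and the $n$ latent $F_i$ with a blocked Gibbs sampler:

- $F_{1:n}$: exact normal full conditional, precision
  $1/\omega^2 + 2/\tau^2 + \beta_F^2/\sigma^2$, vectorized over subjects;
- $(\beta_0, \beta_X, \beta_F, \beta_c)$ and
  $(\gamma_0, \gamma_X, \gamma_c)$: joint multivariate-normal conditional
  per block (one Cholesky solve each);
- $\sigma^2, \omega^2, \tau^2$: inverse-gamma conditionals.

Default sampler configuration: 4 chains, 2,500 iterations each, warmup
fraction 0.5 (1,250 kept per chain, 5,000 total). The tree-depth cap and target
acceptance probability of Hamiltonian samplers are accepted and recorded
in run logs for provenance but are inert here; likewise, a non-centered
reparameterization is unnecessary because the latent block is drawn from
its exact full conditional rather than explored by a trajectory. Chains
start from jittered naive OLS estimates, and runs are exactly
reproducible given seed, data, and settings.

Priors (`prior_spec()`): independent normals on regression coefficients,
default mean 0 and SD 10 — several orders of magnitude wider than any
plausible coefficient on these scales — and near-flat inverse-gamma
(0.001, 0.001) priors on the variances. Inverse gamma is chosen over
half-normal because it keeps every Gibbs update exact; at the sample sizes
involved (hundreds to thousands) the variance posteriors are dominated by
the data, and the posterior–MLE agreement tests confirm the priors are
effectively flat. Informative prior sets are configuration: supply named
means/SDs to `prior_spec()` rather than editing code.

`summarize_posterior()` reports means, SDs, and 2.5/50/97.5 percentiles,
plus split-$\widehat R$ (each chain halved) and effective sample size;
parameters with $\widehat R > 1.01$ raise a warning. `compare_models()`
applies the same ≥ 10% change-in-estimate rule to posterior-mean PFAS
coefficients.

Numerical corners handled explicitly: $\tau^2 = 0$ data (identical
replicates) drive the $\tau^2$ posterior to a numerically tiny value and
pin the latent draws to the replicate mean, reproducing the naive OLS fit,
as a test verifies; a zero-variance column or an exactly collinear design
raises an error naming the offending columns; the marginal likelihood
raises a parameter error (rather than returning garbage) when the implied
covariance is not positive definite.

## The synthetic generator

`generate_synthetic()` is the package's study simulator, not a test
fixture: exposures are log-normal (right-skewed, like serum PFAS),
covariates emulate an adult NHANES-like sample (truncated-normal age,
5-level race/ethnicity, ordinal smoking, log-normal intakes and
income-to-poverty ratio, seven survey waves), the latent fiber and outcome
follow the model above, and the two recall days are written back to the
raw scale by inverting the shift-log and energy-adjustment transforms with
fixed coefficients, so the full preprocessing path can be exercised
round-trip. All draws flow from one seeded generator stream; regenerating
with the same arguments is byte-identical.

Default generating values are chosen once to make a synthetic run resemble
the target setting, and are illustrative rather than estimates:
$\beta_X = 2.42\times10^{-3}$ per ng/mL with $\gamma_X = -0.006$ and
$\beta_F = -0.03$, so the *unadjusted* PFAS coefficient sits near
$2.6\times10^{-3}$ and full adjustment for true fiber would shrink it by
about 7%; $\sigma = 0.17$ (the residual SD of ln-cholesterol);
$\omega^2 = 0.007$ and $\tau^2 = 0.0035$, giving the two-day mean a
reliability of $\lambda = 0.8$ — attenuation of the same order as the
naive-versus-corrected gap such analyses typically report. PFOA is
log-normal with median 2.2 ng/mL.

What the generator does *not* emulate: survey weights and oversampling
design, item nonresponse, systematic recall bias (the model itself assumes
unbiased error), seasonal or weekday effects in intake, and any
non-Gaussianity in the latent fiber distribution. Passing tests therefore
demonstrate that the estimators are correct *under the stated model*, not
that the model is correct for real dietary data. Two small realism
compromises are documented rather than hidden: raw-scale reconstructed
intakes are floored at zero (they can go slightly negative for extreme
draws; well under 1% of rows at the default scales), and the non-latent
fiber column (total when soluble carries the latent structure) is filled
by a noisy proportional link purely to keep the schema complete.

## Problem sizes and design choices in the test harness

The suite validates each claim at the smallest size that gives it power:
quadrature equivalence on 5 subjects; normal-equations equivalence at
n ≤ 100; attenuation identities at n = 50,000; marginal-MLE recovery at
n = 20,000; posterior–MLE agreement at n = 1,000; credible-interval
calibration with 50 replicates at n = 500; moment identities at n = 10⁶.
Property tests that compare estimators on the *same* data (for example,
that the posterior fiber slope is more inverse than the naive OLS slope in
at least 90% of replicates) use a stronger-signal parameter set
($\beta_F = -0.5$, $\lambda = 0.5$), because at the default effect sizes
the ordering would be dominated by sampling noise rather than by the
methods — the property under test is about the estimators, not about any
particular effect size.

## Known limitations

- The latent-fiber model is jointly Gaussian on the transformed scales;
  skewed or heavy-tailed measurement error, and biased recall, are outside
  it.
- Only the confounder is treated as mismeasured; exposure and covariates
  are taken as error-free.
- Survey design (weights, clustering) is intentionally not modeled; the
  regressions condition on the variables that drove the sampling fractions
  instead.
- The change-in-estimate criterion is a heuristic with a conventional 10%
  threshold; it is reported, not defended.
- The Gibbs sampler mixes more slowly for $(\beta_F, \omega^2)$ than for
  the other blocks when $\tau^2/\omega^2$ is large (the latent block is
  then weakly identified); the split-$\widehat R$ warning threshold of
  1.01 surfaces this, and longer chains resolve it.
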
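# pfasfiber

Does dietary fiber confound the association between serum cholesterol and
serum PFAS? `pfasfiber` is an R package for epidemiologists asking exactly
that kind of question: it assesses confounding by a covariate that is only
observed through noisy replicate measurements, using the two 24-hour
dietary recalls of an NHANES-style survey as replicates of latent
long-term fiber intake.

Fiber plausibly suppresses both serum cholesterol (soluble fiber is a
bile-acid sequestrant) and serum PFAS (increased fecal excretion), so an
unadjusted cholesterol–PFAS regression is biased upward. But adjusting for
a *mismeasured* confounder removes only part of the bias: with reliability
λ = ω²/(ω² + τ²/k) for the mean of k replicates, the naive fiber slope
attenuates to λβ_F and the naive PFAS slope converges to
β_X + γ_X β_F (1 − λ), leaving residual confounding behind.

## The model

For subject *i*, with Y = ln(total cholesterol, mg/dL), X = one PFAS
analyte (ng/mL), C = encoded secondary covariates, F = latent fiber on the
ln(shifted, energy-adjusted g/d) scale, and F*₁, F*₂ the two transformed
recall days:

    Y  | X, F, C ~ N(β₀ + β_X X + β_F F + β_c'C, σ²)
    F  | X, C    ~ N(γ₀ + γ_X X + γ_c'C, ω²)
    F*ⱼ | F      ~ N(F, τ²),  j = 1, 2   (independent, nondifferential, unbiased)

The package provides three fitting routes for the same model surface:

- **Naive OLS** (`fit_ols`, `run_table1`) with the ≥ 10% change-in-estimate
  confounding criterion (`assess_confounding`) and a quadratic-PFAS AIC
  sensitivity check — the reference analysis, in which the confounder is
  treated as observed.
- **Closed-form marginal likelihood** (`marginal_moments`,
  `marginal_loglik`, `marginal_mle`): integrating F out leaves a
  trivariate normal for (F*₁, F*₂, Y | X, C); this gives exact maximum
  likelihood and serves as the independent oracle for the sampler.
- **Bayesian latent-variable fit** (`fit_bayes`): a blocked Gibbs sampler
  over all parameters and the n latent fiber values (the model is fully
  conditionally conjugate), with split-R̂/ESS diagnostics
  (`summarize_posterior`) and a Bayesian change-in-estimate comparison
  (`compare_models`).

Around these sit the data pipeline (dictionary-aware CSV reading, isomer
summation, LOD/√2 imputation, residual-method energy adjustment,
shift-log transform, medication and 2.57-SD outlier exclusions) and a
forward simulator (`generate_synthetic`) that makes every stage testable
with no external data.

## Worked example

```r
library(pfasfiber)

d <- generate_synthetic(3000, seed = 42)      # synthetic NHANES-like study
result <- run_pipeline(
  d$records,
  config = analysis_config(mcmc = list(chains = 2L, iterations = 1000L),
                           seed = 42),
  bayes_analytes = "PFOA", bayes_fiber_types = "soluble")
print(result)
```

```
Pipeline report (n = 2929)

 fiber_variable    fiber_ols  fiber_bayes    pfas_ols  pfas_bayes
           None          N/A          N/A 2.86 (2.05) 2.96 (2.15)
    Total fiber -1.14 (1.22)          N/A 2.61 (2.07)         N/A
  Soluble fiber -3.68 (3.68) -4.82 (4.76) 2.59 (2.07) 2.54 (2.10)

Change-in-estimate (OLS):
  PFOA.total     +8.8%
  PFOA.soluble   +9.5%
  ...
Change-in-estimate (Bayesian):
  PFOA.soluble   +14.1%
```

Reading it: 71 of 3,000 synthetic subjects were excluded by the outlier
screen. PFAS coefficients are displayed × 10³ (so `2.86` means
2.86 × 10⁻³ per ng/mL on ln-cholesterol) and fiber coefficients × 10²,
with error estimates in parentheses (OLS standard errors; Bayesian
posterior SDs). The Bayesian soluble-fiber coefficient (−4.82) is more
inverse than the naive OLS one (−3.68): correcting for the measurement
error in the recalls de-attenuates the fiber slope. The change-in-estimate
lines give the percent change of each analyte's coefficient after fiber
adjustment — at this small synthetic size the estimates are noisy (note
the SEs); the full-size run in `scripts/acceptance.R` is the calibrated
version of this example.

## Package layout

- `R/data_model.R` — record schema, CSV I/O, covariate encoding, config
- `R/preprocess.R` — isomer sums, LOD imputation, energy adjustment,
  shift-log, fiber replicates, exclusion cascade
- `R/ols.R` — OLS fits, change-in-estimate, AIC sensitivity, model grid
- `R/oracle.R` — closed-form marginal likelihood and MLE
- `R/bayes.R` — Gibbs sampler, posterior summaries, diagnostics
- `R/synthetic.R` — study simulator and attenuation algebra
- `R/reporting.R` — pipeline orchestration and display-scaled tables
- `vignettes/fiber-measurement-error.Rmd` — model, assumptions, defaults,
  numerical choices, limitations
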
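# ironbio

Case-control analysis of postmortem brain iron biology.

`ironbio` is an R package for studies that ask whether a psychiatric or
neurological disorder perturbs trace-metal biology in postmortem brain
tissue — prototypically: elevated prefrontal iron, decreased ferritin, and
an elevated iron-to-ferritin ratio in schizophrenia cases relative to
matched controls, with the iron excess concentrated in people who died as
young adults. It provides the full analysis chain for such a study, plus a
calibrated synthetic-cohort generator so the entire pipeline is testable
without any patient data.

## What it does

* **Synthetic cohorts** (`default_study_config()`, `generate_cohort()`,
  `inject_outliers()`): three brain banks with distinct measurement
  scales; control iron rising linear-logarithmically with age while case
  iron is age-flat, mean-shifted (+0.58 control-SD) and over-dispersed
  (variance ratio > 2); ferritin coupled to ln(iron) with a disease
  deficit concentrated in low-iron cases; correlated zinc and copper;
  realistic demographics, medication subsets and missingness.
* **Cohort I/O** (`read_cohort()`, `validate_cohort()`,
  `summarize_demographics()`): a documented CSV schema, invariant checks
  reported as data, and Table-1-style group comparisons (pooled t /
  Pearson chi-square).
* **Harmonization** (`harmonize_cohort()`, `bank_zscores()`,
  `iron_ferritin_ratio()`, `test_distribution()`, `compare_variance()`):
  control-anchored per-bank z-scores `z = (x − control mean)/control SD`,
  the within-subject iron-to-ferritin ratio, a skewness/kurtosis omnibus
  normality test, and variance-heterogeneity tests (F and
  Brown-Forsythe).
* **Robust regression** (`fit_mm()`, `fit_linlog_comparison()`,
  `group_difference()`): an MM-estimator — high-breakdown S-stage with
  seeded elemental-set subsampling, then an efficiency-tuned (85% or 95%)
  IRWLS M-step with Tukey bisquare loss — with sandwich standard errors;
  robust linear vs linear-logarithmic model comparison.
* **Serial cutoff scans** (`scan_age_cutoffs()`, `scan_iron_cutoffs()`,
  `select_cutoff()`, `subcohort_contrast()`): covariate-adjusted logistic
  odds-ratio profiles over 2-year age cutoffs (from 31) and 0.1-SD iron
  cutoffs (from −1 SD), with Pregibon delta-beta influence exclusion and
  data-driven operating-cutoff selection.
* **Discrimination** (`roc_auc()`, `auc_bootstrap_ci()`,
  `optimal_cutoff()`, `build_risk_flags()`, `combined_classifier()`):
  rank AUC with bias-corrected stratified bootstrap CIs, Youden-optimal
  cutoffs, and the combined three-flag classifier (high iron in the
  young, low ferritin at low iron, high ratio overall) with exact
  binomial CIs on sensitivity/specificity/accuracy.
* **Confounder machinery** (`propensity_match()`, `mediation()`,
  `medication_association()`): greedy propensity matching with regression
  adjustment, single-mediator product-of-coefficients analysis with
  bootstrap CIs, and permutation-backed medication association tests.

The statistical core in standard notation: per bank *b*, analyte *x*,
harmonized scores are `z = (x − m_b)/s_b` with `m_b`, `s_b` the control
mean and SD; group effects are the diagnosis coefficient of the robust
model `z ~ β₀ + β₁·diagnosis (+ covariates)`, where β̂ solves the
MM-estimating equations `Σ ψ_c((z_i − x_iᵀβ)/σ̂) x_i = 0` with σ̂ the
S-scale and ψ the bisquare score; scan entries report
`OR = exp(γ̂)` from `logit P(case) = α + γ·(adjusted analyte, SD units)`.

## Worked example

```r
library(ironbio)

cohort <- generate_cohort(default_study_config(seed = 4))
ztab   <- harmonize_cohort(cohort)

group_difference(ztab, "iron")
#> MM-estimator robust fit (efficiency 0.85, c_S = 1.5476, c_M = 3.4437)
#>           estimate     se       t      p  ci_low ci_high
#> intercept  -0.0179 0.1504 -0.1192 0.9053 -0.3148  0.2789
#> diagnosis   0.6396 0.2120  3.0164 0.0030  0.2210  1.0582
#> Residual S-scale: 1.2947 on 169 df; converged in 20 iterations

compare_variance(ztab$z_iron[ztab$diagnosis == "control"],
                 ztab$z_iron[ztab$diagnosis == "schizophrenia"])
#> Variance comparison: case 2.764 / control 0.976 = ratio 2.831
#>   F test:          F = 2.831, p = 3.112e-06
#>   Brown-Forsythe:  F = 13.118, p = 0.0003864
```

The diagnosis row says cases run 0.64 control-SD higher in harmonized
prefrontal iron (95% CI 0.22–1.06; this cohort's planted effect is
0.58), and the variance comparison shows the case group nearly three
times as dispersed — both hallmarks the pipeline is built to detect.
Stratifying the covariate-adjusted signal at age 35:

```r
cc <- subcohort_contrast(ztab, cohort, list("age", 35), "iron",
                         c("sex", "ancestry", "ph", "pmi"))
#> adjusted iron contrast: young 2.56 SD, older 0.63 SD
```

The case-control iron difference is several-fold larger among subjects
who died before 35 — the loss-of-age-accumulation signature.

## Documentation

The methods vignette (`vignettes/iron-biology-methods.Rmd`) documents the
model assumptions, every tunable constant (tuning constants, breakdown
points, calipers, grids, thresholds) with its default and rationale, what
the synthetic generator does and does not emulate, and known limitations.
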
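---
title: "Risk-based assessment of treatment-effect heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-based assessment of treatment-effect heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskhte)
```

## The problem

A randomized trial reports one overall treatment effect, but that average
can hide clinically important variation: the same drug may help patients
with a poor prognosis and harm patients with a good one. Traditional
one-variable-at-a-time subgroup analyses (men vs. women, old vs. young)
are poorly suited to detecting such variation — they suffer from
multiplicity, low power, and, more fundamentally, from the fact that a
single variable rarely separates patients by prognosis, because risk
factors act jointly.

The *risk-modeling* approach recommended by the PATH (Predictive
Approaches to Treatment effect Heterogeneity) statement addresses this by
stratifying patients on their predicted baseline outcome probability from
a multivariable model, and then asking whether the treatment benefit
varies across those risk strata. `riskhte` implements that workflow for
binary-outcome parallel-arm trials, together with a synthetic trial
generator that emulates a large thrombolysis stroke trial so that every
stage can be exercised and validated without any data download.

## The four-step procedure

Let $y_i \in \{0, 1\}$ be the favorable outcome (in the emulated stroke
setting: alive and independent, Oxford Handicap Score 0–2 at 6 months),
$t_i \in \{0, 1\}$ the randomized treatment, and $x_i$ the baseline
covariates.

1. **Treatment-blinded risk model** (`fit_risk_model()`). A multivariable
   logistic regression $\operatorname{logit} P(y_i = 1) = \beta_0 +
   \beta^\top x_i$ fit on all complete-case patients, *without* the
   allocated treatment among the covariates. Its linear predictor
   $\mathrm{LP}_i$ and predicted probability $\hat p_i =
   \operatorname{expit}(\mathrm{LP}_i)$ describe baseline prognosis.
   Discrimination and accuracy are summarized by the c statistic and
   Brier score; calibration by the logistic recalibration intercept and
   slope.

2. **Interaction test** (`lr_interaction_test()`). Treatment-effect
   heterogeneity over baseline risk is tested by a likelihood-ratio test
   comparing `outcome ~ treatment + LP` against
   `outcome ~ treatment + LP + treatment:LP`, on 1 df. The *full
   continuous* linear predictor is used, so the test result does not
   depend on how patients are later binned; the statistic is invariant to
   affine rescaling of the LP, so centering conventions are immaterial.

3. **Risk stratification** (`quantile_bins()`). Patients are binned into
   quantile groups (quartiles Q1–Q4 by default) of $\hat p_i$. Binning is
   presentation, not inference.

4. **Treatment benefit per stratum** (`risk_difference()`,
   `stratified_effects()`). Benefit is expressed on the absolute
   risk-difference scale, $\mathrm{RD} = \hat p_T - \hat p_C$, with the
   unpooled-variance Wald 95% CI
   $\mathrm{RD} \pm 1.959964\sqrt{p_T(1-p_T)/n_T + p_C(1-p_C)/n_C}$ and a
   pooled-variance two-proportion z test for the overall effect. The same
   machinery evaluates traditional one-variable subgroups (by default age
   dichotomized at 80 years and sex) for contrast.

`run_analysis()` chains the steps, returning the complete-case report,
the machine-readable odds-ratio table, the interaction test, stratum and
subgroup effects, per-group probability-distribution summaries with
pairwise overlap coefficients, and the data needed to redraw the two
standard displays (ridgeline-style probability densities per group;
benefit versus baseline risk with the ATE band).

## The synthetic trial generator

`generate_trial()` draws trials from the model

$$\operatorname{logit} P(y_i = 1 \mid x_i, t_i) =
  \mathrm{LP}_i + t_i\,\bigl(\delta + \gamma\,(\mathrm{LP}_i -
  \overline{\mathrm{LP}})\bigr), \qquad
  \mathrm{LP}_i = \beta_0 + \beta^\top x_i ,$$

with treatment assigned independently with probability
`allocation_ratio` (0.5 by default). The interaction is parameterized on
the *centered* linear predictor, so $\delta$ is the log-odds effect for a
patient at average risk and $\gamma$ (log-odds per LP unit) controls
heterogeneity; $\gamma = 0$ recovers a homogeneous effect and is the null
of the interaction test.

`ist3_trial_config()` fixes the generator to emulate a large
thrombolysis stroke trial (N = 3035 by default):

* **Covariate marginals** match the published baseline table: age
  truncated Normal(78, 10) on [18, 100]; NIHSS a rounded Gamma(2.053,
  rate 0.1614), which reproduces the printed median 11 and IQR [6, 17];
  total GCS a rounded truncated Normal(14.3, 2.0) on [2.5, 15.49]
  (median 14, IQR [12, 15]); blood pressures and weight Normals matched
  to the printed medians/IQRs; binary and categorical covariates drawn at
  the printed frequencies.
* **Outcome coefficients** equal the log odds ratios of the published
  treatment-blinded model (age 0.96 per year, NIHSS 0.83 per point, …).
  Odds ratios printed as exactly 1.00 enter as 0; diastolic pressure,
  printed as 1.00 with CI 0.99–1.00, enters as 0.995.
* **Calibrated constants.** Three parameters are not printed anywhere
  and were solved once by Monte-Carlo integration over the covariate
  distribution, then frozen: the intercept (5.474056) makes the marginal
  favorable-outcome prevalence 35.7%; the default `treatment_main_effect`
  (0.0983) and `interaction_strength` (−0.286) jointly make the marginal
  risk difference −1.5% and give the interaction test an expected Wald
  z of 3.62 (p ≈ 3×10⁻⁴) at N ≈ 3010 — the published overall pattern of
  a null average effect masking benefit at low baseline probability and
  harm at high.

All randomness flows from the single integer `seed`; the same
configuration and seed reproduce the table bit for bit, and the caller's
RNG state is never disturbed. `inject_missingness()` blanks covariate
cells completely at random (a per-cell rate of 0.00055 leaves roughly 25
of 3035 rows incomplete, the scale of missingness the emulated trial's
complete-case step removes).

**What the generator does *not* emulate.** Covariates are drawn
independently — real prognostic factors cluster in patients, which widens
the true linear-predictor distribution. One visible consequence: the
emulated model's c statistic is about 0.78, below the 0.83 a real trial
of this kind reports, precisely because independence narrows the spread
of prognosis. The generator also has no informative missingness, no
time-to-event structure, and no site/cluster effects. Green tests on
synthetic data therefore validate the *machinery* (estimators, test
calibration, interval coverage, determinism), not the real-data
performance of any particular risk model.

## Numerical and design choices

* **Fitting.** Maximum likelihood via iteratively reweighted least
  squares (the standard GLM engine), convergence tolerance 1e-10, at
  most 100 iterations; the coefficient covariance is the inverse observed
  information at the optimum. A coefficient magnitude above 15 log-odds
  units is reported as a separation error rather than a silently diverged
  estimate; rank-deficient designs and single-level categorical
  predictors raise degenerate-design errors. A scale-invariant
  eigenvalue diagnostic warns on near-collinear designs (relevant when a
  total score is entered alongside its components, as the GCS is here).
* **Reference levels** are the first level declared in the schema,
  mirroring the layout of the published table, so the direction of every
  odds ratio matches the printed one. Confidence intervals are Wald on
  the log-odds scale with z = 1.959964, exponentiated.
* **Quantile definition.** Linear interpolation of order statistics
  (type 7, the default of mainstream statistical environments). A patient
  lands in the lowest stratum whose half-open interval
  $[\text{edge}_{lo}, \text{edge}_{hi})$ contains its probability; the
  top interval is closed; a value equal to a cut point goes to the higher
  stratum, deterministically. More than 50% of probabilities tied at one
  value is reported as a degenerate stratification.
* **Stratum benefit: empirical vs. model-based.** The stratum estimates
  are empirical count-based risk differences. The benefit curve implied
  by the step-2 interaction model, evaluated over the LP range
  (`model_rd_curve()`), is exported alongside them for plotting; the two
  answer slightly different questions and both are provided rather than
  conflating them.
* **Age subgroup split at 80 years.** The published analysis never
  states its age categories; 80 is near the emulated cohort's median
  (81) and is configurable (`subgroups = list(age = 75, ...)`); reports
  carry the chosen threshold in their labels.
* **Densities and overlap.** Per-group probability densities use a
  Gaussian kernel evaluated on a fixed 512-point grid over [0, 1],
  renormalized on the grid (boundary mass would otherwise leak); the
  overlap coefficient is the trapezoid integral of the pointwise minimum
  of two densities. Groups with fewer than 2 members keep their summary
  but omit the density.
* **In-sample linear predictor.** Step 2 reuses the LP estimated on the
  same patients, treating it as a fixed covariate; no estimation
  uncertainty is propagated from step 1. This "apparent" reuse can be
  optimistic, and is the standard practice the workflow mirrors.
* **Missing data** are handled exclusively by complete-case filtering on
  treatment, outcome and all model predictors (scope configurable); no
  imputation of any kind. `read_trial_csv()` accepts empty cells, `NA`
  and `NaN` (case-insensitive) as missing.

## Validation and the simulation sizes used

The test suite validates each stage against independent oracles:
closed-form logistic fits (intercept-only; a 2×2 table's log odds
ratio), exhaustive pair enumeration for the c statistic, a
profile-likelihood grid for the LR statistic, a parametric bootstrap for
the Wald risk-difference interval, and the closed-form Normal overlap
coefficient. Simulation-based checks use sizes chosen to keep Monte-Carlo
error well below the asserted tolerances while running in minutes: test
size under the null at n = 2000 with 1000 replicates (the 95% band for a
true 5% rate is [3.7%, 6.4%]); power monotonicity over
$\gamma \in \{0, 0.2, 0.4, 0.8\}$ with 150 common-random-number
replicates; coefficient recovery on 20 control arms of ~50 000 patients
(each generative coefficient within 3 SE in ≥ 19 of 20 seeds); stratum-CI
coverage at n = 5000 over 200 replicates against the generative
per-stratum truth.

## Known limitations

* The risk model is internal (fit on the trial itself); externally
  developed models are not supported as inputs.
* Effect-score approaches (modeling covariate-by-treatment interactions
  beyond the LP) are out of scope, as are ordinal or utility-weighted
  benefit scales, model-based standard errors as the primary CI, and
  imputation.
* The empirical stratum CIs are plain Wald intervals; at very small
  stratum-arm event counts their coverage degrades, and the
  operating-characteristics tooling (`run_operating_characteristics()`)
  is the honest way to quantify that for a planned configuration.
* The field-name mapping shipped for the deposited stroke-trial export
  (`inst/extdata/ist3_field_mapping.yaml`) is a template: raw field
  names must be verified against that dataset's data dictionary before
  use.
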
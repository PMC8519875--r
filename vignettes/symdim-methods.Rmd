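---
title: "Predicting symptom-dimension change across sites: models, transforms, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting symptom-dimension change across sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Antidepressant response after electroconvulsive therapy (ECT) is usually
tracked with a total score on the 17-item Hamilton Depression Rating Scale
(HDRS-17). Total scores blur distinct symptom constellations. `symdim`
predicts treatment-related *change along three latent symptom dimensions*
of the HDRS-17 — somatic disturbances (SoD, 8 items), core mood and
anhedonia (CMA, 4 items), and insomnia (3 items; the suicide and insight
items load on no dimension) — from clinical and demographic covariates and
regional brain-volume-change features, in cohorts pooled across several
acquisition sites. Two benchmark outcomes, the HDRS-6 (Bech) and HDRS-17
totals, run through the identical pipeline for comparison.

Dimension scores are unit-weight sums over each dimension's item set, and
change is post-treatment minus baseline (negative = improvement). Whether
the original analysis used loading-weighted rather than unit-weight scores
is not determinable from the available description; unit sums are the
default and a per-item weight map can be supplied to `score_dimensions()`.

## The estimation pipeline

For each outcome, `run_cv()` performs repeated k-fold cross-validation
(default 10 repeats x 10 folds) with a bagged regression-tree ensemble
(default 1,000 CART trees minimizing RMSE; `mtry = p/3`; implemented in
C++ in this package because no forest package is available in the target
environment). Three transforms are fitted *strictly on the training part
of each fold* and applied with frozen parameters to the test part:

1. **Imputation/encoding** (`encoder_fit/apply`): training-median
   (numeric) and training-mode (categorical) imputation; indicator coding
   with the most frequent training level as reference.
2. **Confound residualization** (`residualize_fit/apply`): each imaging
   feature is regressed (OLS, intercept included) on age, sex, BMI,
   primary/secondary electrode placement, and the pretreatment severity of
   the outcome's own scale; test features are residualized with the
   training betas. Constant covariate columns are absorbed by the
   intercept; genuine collinearity among fold-level indicator columns is
   pruned by a QR step before the fit.
3. **Batch harmonization** (`harmonize_fit/apply`): the standard
   parametric location/scale model. Features are standardized against a
   pooled grand mean and variance, per-site locations and scales are
   estimated and, by default, shrunk toward cross-feature priors (normal
   for locations, inverse gamma for scales) by iterated conditional modes
   to tolerance 1e-6; `method = "direct"` skips shrinkage. Site scale
   estimates use the 1/n variance convention so single-site data is
   adjusted by exactly nothing. Because features are residualized first,
   no biological covariates are protected during harmonization by default
   (the `covariates` argument exists for stand-alone use). Transform order
   (residualize, then harmonize) is the pipeline default and configurable.

Folds are stratified by site — otherwise a training fold could lack a site
entirely and the fold's harmonization parameters would be undefined for
some test subjects. Site indicators also enter the predictor set in
`"full"` mode (the study itself included site as a predictor); in
`"imaging_only"` mode only the residualized, harmonized volume features
are used.

Every fit call during cross-validation appends the training row ids to an
audit log; `audit_leakage()` counts train/test overlap across all fit
events and must return zero.

### Headline metrics

Per test fold, R² (`1 - SSres/SStot`, unbounded below and never clamped)
and NRMSE (RMSE divided by the test-set outcome range) are recorded; the
headline `pooled_r2` pools each repeat's test predictions, computes R² per
repeat, and averages over repeats. Both aggregations are kept because fold
distributions and pooled values answer different questions.

Model significance uses permutation tests: the outcome vector is shuffled
across subjects and the *entire* pipeline re-run per shuffle (default 100),
with the add-one p-value `(1 + #{null >= observed})/(1 + n)` — so the
smallest attainable p with 100 shuffles is 1/101. P-values across outcomes
are jointly FDR-adjusted (Benjamini–Hochberg, q = 0.05). Performance
differences between outcomes are compared with a one-way ANOVA over fold
R² values; fold scores from a common resampling are not independent, so
this comparison is approximate by construction.

Feature importance is the permutation-based percent increase in MSE
(PIMSE): each feature column of the evaluation set is shuffled (default 10
times) and the relative MSE increase reported; a feature the ensemble
never uses scores exactly 0. Partial dependence profiles follow the
median-conditioning convention — the model's prediction over a feature's
observed-quantile grid with all other predictors held at their observed
medians — because that is the stated convention of the analysis this
package operationalizes; the conventional marginal-average profile is
available via `convention = "marginal"`.

### Leave-one-site-out validation

`run_loso()` trains on all sites but one and predicts the held-out site.
The held-out site contributed no harmonization parameters, so its subjects
are assigned *pseudo-site labels* by a classification forest trained on
the unharmonized training features (training the classifier on harmonized
features would be self-defeating: harmonization removes the very signature
it must learn), and are then harmonized as if from those sites. With
`use_pseudo_site = FALSE` the run fails, deliberately, to demonstrate why
the approximation exists. Held-out R² may be negative and is reported
as-is; site-level extrapolation beyond the training outcome range is
expected to fail and the package does not hide that.

## The synthetic cohort generator

Real multisite ECT consortium data is access-restricted, so
`generate_cohort()` produces cohorts with the statistical structure the
pipeline assumes, plus the ground truth needed for recovery tests. The
default world is a 110-subject, four-site cohort (27/39/16/28 subjects),
with site-specific age (means 40.9/64.4/52.1/46.1 years), BMI (~26),
sex mix, and electrode-placement distributions; 82 bilateral
FreeSurfer-style regions; 19 subjects flagged with psychotic features
(0/16/3/0 per site, deterministic counts); and a per-site response profile
in which one site improves far less than the rest.

Signal is planted on the *dimension-change scale*: per-site mean-change
offsets, covariate slopes (age, sex, BMI, and the dimension's own baseline
severity — the dominant term, as pretreatment severity is the strongest
predictor in this literature), and sparse regional slopes on a small set
of informative regions (optionally shared across dimensions via
`shared_informative_regions`). Slopes are stated on the SoD scale and
shrunk proportionally for the narrower dimensions. Residual noise is drawn
with a configurable 3x3 correlation (default 0.5 off-diagonal, landing
realized change correlations in the reported 0.2–0.95 range); when
`planted_r2` is set, the noise SD is calibrated against the realized
signal variance so the planted variance fraction is exact by construction.
Post-treatment dimension scores are `baseline + change`, rounded, clipped
to legal ranges, and redistributed to items by largest-remainder
allocation proportional to item maxima. Additive and multiplicative site
batch effects (per-site, per-region shifts ~ N(0, `site_shift_sd`), scales
~ U(`site_scale_range`)) are applied to the volume features *after*
outcome assignment, so cross-site recovery genuinely requires
harmonization.

### What the generator does and does not emulate

It emulates: unequal site sizes, site-covariate confounding,
site-outcome confounding, location/scale batch structure, sparse planted
effects, correlated dimension changes, and integer item-level scores with
legal ranges. It does **not** emulate: item-level psychometric
microstructure (items within a dimension are filled by a deterministic
allocation rule, not an IRT model), non-normal or heavy-tailed volumetric
changes (defaults are normal; configurable), spatially correlated regions,
or scanner effects beyond location/scale. A green recovery test therefore
establishes that the pipeline recovers planted structure under its own
model assumptions — not that it would perform identically on real
consortium data.

Two discretization effects deserve explicit mention, because tests
encountered both. First, rounding and scale-limit clamping attenuate
dimension-change correlations; correlation-recovery checks use worlds with
mean change 0 and centered baselines so the planted correlation is
identifiable. Second, when the mean change is large relative to baseline
(the realistic default), floor clamping makes change genuinely dependent
on baseline severity even with *no planted signal* — a "null" cohort in
the realistic world is not null with respect to the baseline-severity
predictor. Calibration checks of the permutation test therefore use
mean-change-0 null worlds; this is a property of bounded scales, not of
the test.

## Numerical and design choices

* **Ensemble**: bootstrap n-of-n sampling; variance-reduction splits;
  split candidates `mtry = max(p/3, 1)` (regression) or `sqrt(p)`
  (classification); nodes smaller than 5 (regression) are leaves; midpoint
  thresholds, with a guard that treats a split as unsplittable when the
  midpoint rounds onto an endpoint. All randomness flows from R's RNG, so
  `set.seed()` (or the `seed` arguments) makes every run bit-reproducible.
* **Ties in importance ranks** break by feature-name order.
* **Empirical-Bayes iteration** stops when the relative parameter change
  falls below 1e-6 (500-iteration cap); with fewer than two features the
  harmonizer falls back to direct estimates with a warning.
* **Degenerate inputs**: R² is an error on constant actuals; NRMSE on
  zero range; harmonization on any site with fewer than two training
  subjects or a feature constant within a site; `harmonize_apply` on an
  unknown site label (the error text points to pseudo-site labeling).
* **Unseen categorical levels** at the transform API are an error; inside
  cross-validation folds they map to the training reference level, since a
  rare level appearing only in a test fold must not abort the run.
* **Missing covariates** are imputed fold-internally (median/mode);
  imaging features must be complete.

## Limitations

The ensemble is a plain bagged-CART implementation — adequate for the
pipeline's purposes and tested against planted signal, but without the
performance refinements (presorted features, honest splitting options) of
dedicated forest libraries. The harmonizer implements the parametric
empirical-Bayes variant only (no nonparametric priors, no covariance
harmonization, no longitudinal variant). The ANOVA comparison of fold
scores inherits the field's optimistic-independence caveat. Pseudo-site
harmonization substitutes the nearest training site's batch parameters for
the held-out site's own; in worlds where per-site effects are independent,
the benefit is real but modest, and it shows up as cleaner training data
rather than correct test-site adjustment.
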
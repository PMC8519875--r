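# symdim

Leakage-safe multisite prediction of change along latent
depressive-symptom dimensions after electroconvulsive therapy (ECT).

## The problem

Depression symptom heterogeneity limits treatment-response biomarkers:
an HDRS-17 *total* score mixes somatic, mood, and sleep symptoms that may
recover along different neural routes. `symdim` scores HDRS-17 assessments
into three latent dimensions — somatic disturbances (SoD), core mood and
anhedonia (CMA), and insomnia — plus HDRS-6/HDRS-17 benchmark totals, and
predicts each dimension's treatment-related change from clinical and
demographic covariates and regional brain-volume-change features pooled
across acquisition sites. It is written for biostatisticians and
neuroimaging researchers who need a multisite prediction pipeline whose
preprocessing cannot leak test information.

At its core, for outcome change Δy (post − baseline, negative =
improvement), a bagged regression-tree ensemble (1,000 CART trees
minimizing RMSE) is evaluated with repeated site-stratified k-fold
cross-validation (10×10 by default). Inside every fold, fitted strictly on
the training rows and applied frozen to the test rows:

* per-feature confound residualization of the imaging features on age,
  sex, BMI, electrode placements, and pretreatment severity
  (`x_res = x − [1, C] β̂_train`);
* location/scale batch harmonization with empirical-Bayes shrinkage
  (per-site `γ, δ` on standardized features; `x_adj = σ (z − γ*)/δ* + μ`);
* model fit and prediction.

Performance is R² = 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)² and NRMSE = RMSE/(y_max −
y_min); significance via 100-shuffle permutation tests with add-one
p-values, FDR-adjusted across outcomes; importance via the permutation
percent-increase-in-MSE (PIMSE); effect profiles via median-conditioned
partial dependence. Leave-one-site-out validation harmonizes the held-out
site through *pseudo-site labels* predicted by a site classifier trained
on the unharmonized training features. Because the real consortium data is
access-restricted, a synthetic multisite cohort generator with planted
ground truth (site batch effects, sparse regional effects, correlated
dimension changes) backs all recovery and calibration tests.

## Worked example

```r
library(symdim)

gen <- generate_cohort(cohort_config(seed = 42))   # 110 subjects, 4 sites
table(gen$subjects$site)
#> site1 site2 site3 site4
#>    27    39    16    28

round(dimension_change_correlations(gen$subjects), 2)
#>           sod  cma insomnia
#> sod      1.00 0.65     0.70
#> cma      0.65 1.00     0.66
#> insomnia 0.70 0.66     1.00

cv <- run_cv(gen$subjects, "cma", k = 5, repeats = 2,
             num_trees = 200, seed = 11)
cv
#> Cross-validated model: outcome=cma predictors=full (2x5-fold)
#>   pooled R^2 = 0.2022  pooled NRMSE = 0.2038
#>   per-fold R^2: median 0.160 [-0.012, 0.415]

audit_leakage(cv)   # train/test row overlap across all fit events
#> [1] 0
```

The pooled R² (mean over repeats of each repeat's pooled test-prediction
R²) says ~20% of CMA-change variance is explained out-of-sample in this
synthetic world; the fold distribution shows the spread a 22-subject test
fold produces; the audit confirms no fit ever saw a test row. The same
call with the default settings (`k = 10, repeats = 10, num_trees = 1000`)
is the full-scale analysis.

Other entry points: `score_dimensions()` / `score_cohort()` (dimension
scoring), `run_loso()` (leave-one-site-out with `use_pseudo_site`),
`permutation_test()`, `pimse_importance()`, `partial_dependence()`,
`compare_models()`, `run_pipeline()` (end-to-end with artifacts), and a
CLI (`inst/exec/symdim`) with `simulate`, `score-dimensions`, `run-cv`,
`run-loso`, and `report` subcommands.

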
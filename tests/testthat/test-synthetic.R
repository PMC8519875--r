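test_that("default config reproduces the study cohort shape", {
  gen <- default_cohort()
  expect_equal(nrow(gen$subjects), 110L)
  expect_equal(unname(table(gen$subjects$site)),
               c(27L, 39L, 16L, 28L), ignore_attr = TRUE)
  expect_equal(sum(gen$subjects$psychotic), 19L)
  expect_length(grep("^vol_change_", names(gen$subjects)), 82L)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- cohort_config(n_per_site = rep(10L, 3), n_regions = 12L, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth$site_shifts, b$truth$site_shifts)
})

test_that("config invariants are enforced with named errors", {
  expect_error(cohort_config(n_informative_regions = 100, n_regions = 20),
               "n_informative_regions")
  bad_corr <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(cohort_config(dim_change_corr = bad_corr),
               "positive semi-definite")
  expect_error(cohort_config(site_scale_range = c(2, 1)),
               "site_scale_range")
  expect_error(cohort_config(site_scale_range = c(-1, 1)),
               "site_scale_range")
  expect_error(cohort_config(noise_sd = -2), "noise_sd")
  asym <- diag(3)
  asym[1, 2] <- 0.5
  expect_error(cohort_config(dim_change_corr = asym), "symmetric")
})

test_that("every generated HDRS item is within its legal range", {
  gen <- default_cohort()
  for (ph in c("pre", "post")) {
    items <- as.matrix(gen$subjects[, sprintf("hdrs_%s_%02d", ph, 1:17)])
    expect_true(all(items == round(items)))
    expect_true(all(items >= 0))
    expect_true(all(sweep(items, 2, hdrs_items$max, `<=`)))
  }
})

test_that("null world has no region-outcome correlation", {
  cfg <- cohort_config(
    n_per_site = rep(60L, 4), n_regions = 20L,
    covariate_effect_sizes = c(age = 0, sex = 0, bmi = 0,
                               baseline_severity = 0),
    region_effect_size = 0, site_change_shift = rep(0, 4),
    noise_sd = 2.5, seed = 31)
  gen <- generate_cohort(cfg)
  ch <- as.matrix(score_cohort(gen$subjects)$change[, c("sod", "cma",
                                                        "insomnia")])
  x <- imaging_matrix(gen$subjects)
  n <- nrow(x)
  cors <- stats::cor(x, ch)
  # per-pair null band is 3/sqrt(n); the max over 60 region-dimension
  # pairs needs the familywise-safe 4/sqrt(n)
  expect_lt(max(abs(cors)), 4 / sqrt(n))
  expect_gt(mean(abs(cors) < 3 / sqrt(n)), 0.95)
})

test_that("planted R2 is recoverable by the design-matrix oracle", {
  cfg <- cohort_config(n_per_site = rep(100L, 4), planted_r2 = 0.4,
                       seed = 5)
  gen <- generate_cohort(cfg)
  sc <- score_cohort(gen$subjects)
  for (k in c("sod", "cma", "insomnia")) {
    ols <- stats::lm(sc$change[[k]] ~ gen$truth$signal[, k])
    expect_lt(abs(summary(ols)$r.squared - 0.4), 0.1)
  }
})

test_that("dimension-change correlations behave as planted", {
  # identity residual correlation, noise dominant -> near-zero off-diags
  # mean change 0, centered baselines, and per-dimension noise keep post
  # scores off the scale limits: clamping and rounding otherwise
  # attenuate (or inject) correlation beyond the sampling band
  cfg0 <- cohort_config(
    n_per_site = rep(250L, 4),
    covariate_effect_sizes = c(age = 0, sex = 0, bmi = 0,
                               baseline_severity = 0),
    region_effect_size = 0, site_change_shift = rep(0, 4),
    mean_change = c(sod = 0, cma = 0, insomnia = 0),
    baseline_mu = c(sod = 11, cma = 7.5, insomnia = 3),
    dim_change_corr = diag(3), noise_sd = c(2, 2, 1.2), seed = 17)
  cc0 <- dimension_change_correlations(generate_cohort(cfg0)$subjects)
  off <- cc0[upper.tri(cc0)]
  expect_lt(max(abs(off)), 3 / sqrt(1000))
  expect_equal(cc0, t(cc0))
  expect_equal(unname(diag(cc0)), rep(1, 3))
  # planted 0.6 recovered within the Fisher-z sampling band at n=1000
  cfg6 <- cfg0
  cfg6$dim_change_corr <- matrix(0.6, 3, 3)
  diag(cfg6$dim_change_corr) <- 1
  cc6 <- dimension_change_correlations(generate_cohort(cfg6)$subjects)
  expect_true(all(abs(cc6[upper.tri(cc6)] - 0.6) < 0.1))
  # default config at n~1000: all off-diagonals within the loose band
  ccd <- dimension_change_correlations(
    generate_cohort(cohort_config(n_per_site = rep(250L, 4),
                                  seed = 23))$subjects)
  expect_true(all(ccd[upper.tri(ccd)] > 0.1 & ccd[upper.tri(ccd)] < 0.95))
  expect_error(
    dimension_change_correlations(default_cohort()$subjects[1:2, ]),
    "fewer than 3")
})

test_that("oracle batch-effect removal restores cross-site homogeneity", {
  gen <- generate_cohort(cohort_config(n_per_site = rep(40L, 4),
                                       n_regions = 40L, site_shift_sd = 0.6,
                                       seed = 8))
  x <- imaging_matrix(gen$subjects)
  s <- gen$subjects$site
  oracle <- (x - gen$truth$site_shifts[s, ]) / gen$truth$site_scales[s, ]
  f <- site_f_stats(oracle, s)
  crit <- stats::qf(0.95, 3, nrow(x) - 4)
  expect_gte(mean(f < crit), 0.9)
})

test_that("oracle linear-fit R2 is monotone in region_effect_size", {
  r2s <- vapply(c(0, 0.5, 1), function(es) {
    cfg <- cohort_config(n_per_site = rep(50L, 4), region_effect_size = es,
                         noise_sd = 2.5, seed = 77)
    gen <- generate_cohort(cfg)
    # oracle fit on the generator's continuous outcome (pre item
    # discretization), identical noise realization across effect sizes
    summary(stats::lm(gen$truth$delta_target[, "sod"] ~
                        gen$truth$signal[, "sod"]))$r.squared
  }, numeric(1))
  expect_true(all(diff(r2s) >= 0))
})
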
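test_that("fold plans partition subjects per repeat, stratified by site", {
  ids <- sprintf("S%03d", 1:110)
  site <- rep(c("a", "b", "c", "d"), c(27, 39, 16, 28))
  plans <- make_folds(ids, k = 10, repeats = 10, seed = 3, site = site)
  expect_length(plans, 100L)
  for (r in 1:10) {
    pr <- Filter(function(p) p$repeat_index == r, plans)
    test_ids <- unlist(lapply(pr, `[[`, "test_ids"))
    expect_setequal(test_ids, ids)          # union over folds = everyone
    expect_equal(anyDuplicated(test_ids), 0L)  # exactly one test fold
    for (p in pr) {
      expect_length(intersect(p$train_ids, p$test_ids), 0L)
      expect_setequal(c(p$train_ids, p$test_ids), ids)
    }
  }
  # each subject appears in exactly `repeats` test sets overall
  all_tests <- table(unlist(lapply(plans, `[[`, "test_ids")))
  expect_true(all(all_tests == 10L))
  # deterministic
  expect_identical(plans, make_folds(ids, 10, 10, seed = 3, site = site))
  # leave-one-out shape
  loo <- make_folds(ids[1:10], k = 10, repeats = 1, seed = 1)
  expect_true(all(vapply(loo, function(p) length(p$test_ids), 1L) == 1L))
  expect_error(make_folds(ids[1:5], k = 10), "exceeds")
})

test_that("run_cv is deterministic, leak-free, and honest on noise", {
  gen <- small_cohort()
  set.seed(1001)
  noise <- stats::rnorm(nrow(gen$subjects))
  cv <- run_cv(gen$subjects, "sod", k = 4, repeats = 2, num_trees = 80,
               seed = 5, outcome_values = noise)
  expect_lte(cv$pooled_r2, 0.05)
  expect_lte(stats::median(cv$fold_r2, na.rm = TRUE), 0)
  expect_equal(audit_leakage(cv), 0L)
  # every subject has exactly `repeats` test predictions
  expect_true(all(table(cv$predictions$id) == 2L))
  expect_equal(length(cv$fold_r2), 8L)
  cv2 <- run_cv(gen$subjects, "sod", k = 4, repeats = 2, num_trees = 80,
                seed = 5, outcome_values = noise)
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("pooled R2 agrees with the formula oracle on pooled predictions", {
  gen <- small_cohort()
  cv <- run_cv(gen$subjects, "cma", k = 4, repeats = 2, num_trees = 80,
               seed = 11)
  by_rep <- split(cv$predictions, cv$predictions$rep)
  manual <- vapply(by_rep, function(d)
    1 - sum((d$actual - d$predicted)^2) /
      sum((d$actual - mean(d$actual))^2), numeric(1))
  expect_equal(cv$pooled_r2, mean(manual))
})

test_that("oracle injection gives perfect scores", {
  gen <- small_cohort()
  cv <- run_cv(gen$subjects, "insomnia", k = 3, repeats = 1, num_trees = 10,
               seed = 2, .inject_oracle = TRUE)
  expect_equal(cv$pooled_r2, 1)
  expect_equal(cv$pooled_nrmse, 0)
})

test_that("imaging_only mode uses no clinical/demographic predictor", {
  gen <- small_cohort()
  cv <- run_cv(gen$subjects, "sod", predictors = "imaging_only", k = 3,
               repeats = 1, num_trees = 30, seed = 4, keep_models = TRUE)
  feats <- cv$models[[1]]$fit$feature_names
  expect_true(all(grepl("^vol_change_", feats)))
  cv_full <- run_cv(gen$subjects, "sod", predictors = "full", k = 3,
                    repeats = 1, num_trees = 30, seed = 4,
                    keep_models = TRUE)
  expect_true(any(grepl("^age$|^bmi$|^baseline_severity$",
                        cv_full$models[[1]]$fit$feature_names)))
})

test_that("run_loso holds out each site once and permits negative R2", {
  gen <- small_cohort()
  lo <- run_loso(gen$subjects, "cma", num_trees = 60, seed = 6)
  expect_length(lo$sites, 4L)
  for (r in lo$sites) {
    expect_true(all(gen$subjects$site[match(r$predictions$id,
                                            gen$subjects$id)] == r$site))
    expect_true(is.finite(r$r2))  # negative allowed, never clamped
  }
  expect_error(run_loso(gen$subjects[gen$subjects$site %in%
                                       c("site1", "site2"), ], "cma"),
               ">= 3 sites")
  # without pseudo-site labels, harmonizing an unseen site fails by design
  expect_error(run_loso(gen$subjects, "cma", use_pseudo_site = FALSE,
                        num_trees = 10, seed = 1), "pseudo")
})

test_that("permutation_test counts and cross_factor self-check hold", {
  gen <- small_cohort()
  runner <- make_cv_runner(k = 3, repeats = 1, num_trees = 40, seed = 21)
  pt <- permutation_test(runner, gen$subjects, "cma", n_shuffles = 5,
                         seed = 31)
  expect_length(pt$null_r2, 5L)
  expect_equal(pt$p_value,
               permutation_p(pt$observed_r2, pt$null_r2))
  expect_gte(pt$p_value, 1 / 6)
  # A = B reproduces the original result exactly
  cv <- runner(gen$subjects, "cma", NULL)
  self <- cross_factor_predict(cv, gen$subjects, "cma")
  expect_equal(self$pooled_r2, cv$pooled_r2)
})

test_that("cross-factor predictions separate disjoint vs shared signal", {
  # disjoint informative regions, independent residuals, no shared
  # covariate or site effects: model for one dimension should not
  # transfer to the other
  cfg_dis <- cohort_config(
    n_per_site = rep(60L, 4), n_regions = 30L,
    n_informative_regions = 6L, region_effect_size = 1,
    covariate_effect_sizes = c(age = 0, sex = 0, bmi = 0,
                               baseline_severity = 0),
    site_change_shift = rep(0, 4), site_shift_sd = 0,
    site_scale_range = c(1, 1), dim_change_corr = diag(3),
    planted_r2 = 0.5, seed = 41)
  gen <- generate_cohort(cfg_dis)
  # independent residuals + no shared covariate/site signal: even with an
  # incidental overlap in informative sets, transfer must be weaker than
  # the within-dimension fit
  cv <- run_cv(gen$subjects, "sod", predictors = "imaging_only", k = 4,
               repeats = 1, num_trees = 150, seed = 3)
  crossed <- cross_factor_predict(cv, gen$subjects, "cma")
  expect_lt(crossed$pooled_r2, cv$pooled_r2)
  # highly correlated outcomes with fully shared signal (same informative
  # regions, same covariate slopes, no dimension-specific baseline term)
  # transfer well, mirroring overlapping neural substrates
  cfg_shared <- cohort_config(
    n_per_site = rep(60L, 4), n_regions = 30L,
    n_informative_regions = 6L, region_effect_size = 1,
    shared_informative_regions = TRUE,
    covariate_effect_sizes = c(age = -0.6, sex = 0, bmi = -0.3,
                               baseline_severity = 0),
    site_change_shift = rep(0, 4), site_shift_sd = 0,
    site_scale_range = c(1, 1),
    dim_change_corr = matrix(c(1, 0.9, 0.9, 0.9, 1, 0.9, 0.9, 0.9, 1),
                             3, 3),
    baseline_mu = c(sod = 11, cma = 11, insomnia = 3.8),
    baseline_sd = c(sod = 3.5, cma = 3.5, insomnia = 1.3),
    mean_change = c(sod = -5, cma = -5, insomnia = -2),
    planted_r2 = 0.5, seed = 43)
  gen2 <- generate_cohort(cfg_shared)
  cv2 <- run_cv(gen2$subjects, "sod", k = 4, repeats = 1, num_trees = 150,
                seed = 3)
  crossed2 <- cross_factor_predict(cv2, gen2$subjects, "cma")
  expect_lt(abs(crossed2$pooled_r2 - cv2$pooled_r2), 0.1)
})

test_that("pimse and pdp behave on engineered models", {
  set.seed(12)
  n <- 250
  x <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * x[, 1] + stats::rnorm(n, 0, 0.2)
  fit <- rf_regression(x, y, num_trees = 300, seed = 8)
  imp <- pimse_importance(fit, x, y, n_permutations = 5, seed = 5)
  expect_equal(imp$feature[imp$rank == 1], "f1")
  expect_setequal(imp$rank, 1:6)
  # a feature the model never saw cannot matter
  x2 <- cbind(x, ghost = stats::rnorm(n))
  imp2 <- pimse_importance(fit, x2[, colnames(x)], y, n_permutations = 3,
                           seed = 1)
  expect_true(all(is.finite(imp2$pimse)))
  fit_c <- rf_regression(cbind(x, dead = rep(1, n)), y, num_trees = 50,
                         seed = 2)
  imp3 <- pimse_importance(fit_c, cbind(x, dead = rep(1, n)), y,
                           n_permutations = 3, seed = 1)
  expect_identical(imp3$pimse[imp3$feature == "dead"], 0)
  # pdp of the linear signal has roughly the planted slope
  grid <- partial_dependence(fit, x, "f1", n_grid = 15)
  inner <- grid$grid_values > -1 & grid$grid_values < 1
  slope <- stats::coef(stats::lm(grid$expected_outcome[inner] ~
                                   grid$grid_values[inner]))[2]
  expect_lt(abs(slope - 2) / 2, 0.25)
  expect_true(all(diff(grid$grid_values) > 0))
  expect_length(grid$expected_outcome, length(grid$grid_values))
  # unused feature -> flat profile; constant feature -> warning
  g2 <- partial_dependence(fit_c, cbind(x, dead = rep(1, n)), "f4")
  expect_lt(max(g2$expected_outcome) - min(g2$expected_outcome),
            0.25 * stats::sd(y))
  expect_warning(partial_dependence(fit_c, cbind(x, dead = rep(1, n)),
                                    "dead"), "constant")
  # marginal convention averages over rows
  g3 <- partial_dependence(fit, x, "f1", n_grid = 5,
                           convention = "marginal")
  expect_equal(g3$others_held_at, "marginal")
})
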
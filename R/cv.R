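# Cross-validation engine. Every transform (imputation/encoding,
# residualization, harmonization) and the ensemble itself are fitted
# strictly inside the training part of each fold; fitted parameters are
# then applied to the test part. Each fit call is written to an audit log
# of training row ids so tests can assert zero train/test overlap.

outcome_names <- c("sod", "cma", "insomnia", "hdrs6", "hdrs17")

outcome_column <- function(outcome) {
  outcome <- match.arg(outcome, outcome_names)
  switch(outcome, hdrs6 = "hdrs6_total", hdrs17 = "hdrs17_total", outcome)
}

#' Build site-stratified repeated k-fold plans
#'
#' Each repeat partitions the subjects into `k` disjoint test folds,
#' stratified by site so every training fold retains at least two subjects
#' from every site (needed by the harmonizer). Deterministic under `seed`.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param k folds per repeat (`k <=` number of subjects).
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @param site optional site label per subject (stratification variable).
#' @return list of fold plans: `repeat_index`, `fold_index`, `train_ids`,
#'   `test_ids`, `seed` (a fold-specific model seed).
#' @export
make_folds <- function(subject_ids, k, repeats = 1L, seed = 1L,
                       site = NULL) {
  n <- length(subject_ids)
  stopifnot(!anyDuplicated(subject_ids))
  if (k > n) stop("make_folds: k exceeds the number of subjects")
  if (is.null(site)) site <- rep("all", n)
  withr::with_seed(as.integer(seed), {
    plans <- list()
    for (r in seq_len(repeats)) {
      fold_of <- integer(n)
      for (s in unique(site)) {
        rows <- which(site == s)
        rows <- rows[sample.int(length(rows))]
        offset <- sample.int(k, 1L)
        fold_of[rows] <- ((seq_along(rows) - 1L + offset) %% k) + 1L
      }
      for (f in seq_len(k)) {
        test <- subject_ids[fold_of == f]
        if (length(test) == 0L) next
        plans[[length(plans) + 1L]] <- list(
          repeat_index = r, fold_index = f,
          train_ids = subject_ids[fold_of != f], test_ids = test,
          seed = sample.int(.Machine$integer.max, 1L))
      }
    }
    plans
  })
}

# Columns forming a full-rank design together with an intercept.
independent_columns <- function(x) {
  qr_d <- qr(cbind(1, x))
  keep_idx <- qr_d$pivot[seq_len(qr_d$rank)]
  sort(keep_idx[keep_idx > 1] - 1L)
}

# Site indicator columns with cohort-wide levels (site identity is public
# study design, not subject-level information, so the level set is fixed
# up front; the indicators themselves carry no test outcome data).
site_indicators <- function(site, levels_all) {
  out <- vapply(levels_all[-1], function(lv) as.numeric(site == lv),
                numeric(length(site)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(site))
  colnames(out) <- paste0("site_", levels_all[-1])
  out
}

# Shared per-fold pipeline: fit transforms + model on the training rows,
# return test predictions. `audit` is an environment collecting fit events.
fit_fold <- function(cohort, y, baseline_sev, tr, te, predictors,
                     residualize, harmonize, harmonize_method, num_trees,
                     mtry, fold_seed, audit, site_levels,
                     pseudo_site = FALSE, pseudo_trees = 500L,
                     inject_oracle = FALSE) {
  log_fit <- function(stage)
    audit$events[[length(audit$events) + 1L]] <-
      list(stage = stage, train_ids = cohort$id[tr], n = length(tr))
  img_cols <- grep("^vol_change_", names(cohort), value = TRUE)
  cov_df <- data.frame(age = cohort$age, sex = cohort$sex, bmi = cohort$bmi,
                       electrode_primary = cohort$electrode_primary,
                       electrode_secondary = cohort$electrode_secondary,
                       baseline_severity = baseline_sev,
                       stringsAsFactors = FALSE)
  enc <- encoder_fit(cov_df[tr, , drop = FALSE])
  log_fit("encoder")
  x_cov_tr <- encoder_apply(enc, cov_df[tr, , drop = FALSE])
  x_cov_te <- encoder_apply(enc, cov_df[te, , drop = FALSE],
                            strict_levels = FALSE)
  # rare categorical levels can make fold designs collinear (e.g. one
  # subject holding two unique levels); drop dependent columns, keeping
  # train and test designs aligned
  keep <- independent_columns(x_cov_tr)
  x_cov_tr <- x_cov_tr[, keep, drop = FALSE]
  x_cov_te <- x_cov_te[, keep, drop = FALSE]
  img_tr <- as.matrix(cohort[tr, img_cols, drop = FALSE])
  img_te <- as.matrix(cohort[te, img_cols, drop = FALSE])
  if (residualize) {
    rp <- residualize_fit(img_tr, x_cov_tr)
    log_fit("residualization")
    img_tr <- residualize_apply(rp, img_tr, x_cov_tr)
    img_te <- residualize_apply(rp, img_te, x_cov_te)
  }
  site_tr <- cohort$site[tr]
  site_te <- cohort$site[te]
  if (harmonize) {
    hp <- harmonize_fit(img_tr, site_tr, method = harmonize_method)
    log_fit("harmonization")
    if (pseudo_site) {
      # the site classifier needs the *unharmonized* features -- after
      # harmonization the site signature it must learn has been removed
      site_te <- pseudo_site_labels(img_tr, site_tr, img_te,
                                    num_trees = pseudo_trees,
                                    seed = fold_seed %% 1000003L)
      log_fit("pseudo_site_classifier")
    }
    img_tr <- hp$adjusted
    img_te <- harmonize_apply(hp, img_te, site_te)
  }
  if (predictors == "full") {
    x_tr <- cbind(x_cov_tr, site_indicators(cohort$site[tr], site_levels),
                  img_tr)
    x_te <- cbind(x_cov_te, site_indicators(cohort$site[te], site_levels),
                  img_te)
  } else {
    x_tr <- img_tr
    x_te <- img_te
  }
  fit <- rf_regression(x_tr, y[tr], num_trees = num_trees, mtry = mtry,
                       seed = fold_seed)
  log_fit("ensemble")
  pred <- if (inject_oracle) y[te] else predict(fit, x_te)
  list(pred = pred, fit = fit, x_te = x_te, x_tr = x_tr)
}

#' Repeated k-fold cross-validated prediction of symptom-dimension change
#'
#' For each fold: covariate imputation/encoding, per-feature confound
#' residualization, and site harmonization are fitted on the training rows
#' and applied to the test rows; a `num_trees`-tree regression ensemble is
#' fitted on the training rows and evaluated on the test rows. In
#' `imaging_only` mode clinical/demographic covariates are regressed out of
#' the imaging features and excluded as predictors; in `full` mode they are
#' predictors alongside the harmonized imaging features and site
#' indicators.
#'
#' @param cohort cohort data.frame ([generate_cohort()]/[read_cohort()]).
#' @param outcome one of `"sod"`, `"cma"`, `"insomnia"`, `"hdrs6"`,
#'   `"hdrs17"` (change scores, post minus baseline).
#' @param predictors `"full"` or `"imaging_only"`.
#' @param k,repeats cross-validation geometry (primary-analysis setting: 10 x 10).
#' @param num_trees regression trees per fold model (primary-analysis setting: 1,000).
#' @param mtry candidate features per split (default p/3).
#' @param seed integer; the run is deterministic given (cohort, seed).
#' @param harmonize,residualize enable/disable the two transforms.
#' @param harmonize_method passed to [harmonize_fit()].
#' @param outcome_values optional replacement outcome vector (one value per
#'   subject) -- used by permutation tests and null-calibration audits;
#'   baseline severity covariates keep their original values.
#' @param keep_models retain per-fold fitted ensembles and transformed test
#'   matrices (memory-heavy; needed for fold-level importance work).
#' @param .inject_oracle internal test hook: bypasses the ensemble and
#'   copies test predictions from the actuals, for metric plumbing checks.
#' @return an object of class `symdim_cv`: `predictions` (subject, repeat,
#'   fold, actual, predicted), `fold_r2`, `fold_nrmse`, `repeat_r2`,
#'   `pooled_r2` (mean of per-repeat pooled R-squared, the headline
#'   metric), `pooled_nrmse`, and the fit-event `audit` log.
#' @export
run_cv <- function(cohort, outcome, predictors = c("full", "imaging_only"),
                   k = 10L, repeats = 10L, num_trees = 1000L, mtry = NULL,
                   seed = 1L, harmonize = TRUE,
                   harmonize_method = "empirical_bayes", residualize = TRUE,
                   outcome_values = NULL, keep_models = FALSE,
                   .inject_oracle = FALSE) {
  predictors <- match.arg(predictors)
  col <- outcome_column(outcome)
  scored <- score_cohort(cohort)
  y <- if (is.null(outcome_values)) scored$change[[col]] else
    as.numeric(outcome_values)
  stopifnot(length(y) == nrow(cohort))
  baseline_sev <- scored$baseline[[col]]
  site_levels <- sort(unique(cohort$site))
  plans <- make_folds(cohort$id, k = k, repeats = repeats, seed = seed,
                      site = cohort$site)
  audit <- new.env(parent = emptyenv())
  audit$events <- list()
  preds <- vector("list", length(plans))
  models <- if (keep_models) vector("list", length(plans)) else NULL
  fold_test_ids <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    tr <- match(pl$train_ids, cohort$id)
    te <- match(pl$test_ids, cohort$id)
    res <- fit_fold(cohort, y, baseline_sev, tr, te, predictors,
                    residualize, harmonize, harmonize_method, num_trees,
                    mtry, pl$seed, audit, site_levels,
                    inject_oracle = .inject_oracle)
    preds[[i]] <- data.frame(id = pl$test_ids, rep = pl$repeat_index,
                             fold = pl$fold_index, actual = y[te],
                             predicted = res$pred,
                             stringsAsFactors = FALSE)
    fold_test_ids[[i]] <- pl$test_ids
    if (keep_models)
      models[[i]] <- list(fit = res$fit, x_te = res$x_te,
                          test_ids = pl$test_ids)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  summarize_cv(predictions, list(
    outcome = outcome, predictors = predictors, k = k, repeats = repeats,
    num_trees = num_trees, seed = seed, harmonize = harmonize,
    harmonize_method = harmonize_method, residualize = residualize),
    audit = list(events = audit$events, test_ids = fold_test_ids),
    models = models)
}

summarize_cv <- function(predictions, config, audit = NULL, models = NULL) {
  by_fold <- split(predictions, list(predictions$rep, predictions$fold),
                   drop = TRUE)
  fold_r2 <- vapply(by_fold, function(d) {
    if (stats::var(d$actual) == 0 || nrow(d) < 2L) NA_real_
    else r_squared(d$actual, d$predicted)
  }, numeric(1))
  fold_nrmse <- vapply(by_fold, function(d) {
    if (max(d$actual) == min(d$actual) || nrow(d) < 2L) NA_real_
    else nrmse(d$actual, d$predicted)
  }, numeric(1))
  by_rep <- split(predictions, predictions$rep)
  repeat_r2 <- vapply(by_rep, function(d) r_squared(d$actual, d$predicted),
                      numeric(1))
  repeat_nrmse <- vapply(by_rep, function(d) nrmse(d$actual, d$predicted),
                         numeric(1))
  structure(
    list(predictions = predictions, fold_r2 = unname(fold_r2),
         fold_nrmse = unname(fold_nrmse), repeat_r2 = unname(repeat_r2),
         pooled_r2 = mean(repeat_r2), pooled_nrmse = mean(repeat_nrmse),
         config = config, audit = audit, models = models),
    class = "symdim_cv")
}

#' @export
print.symdim_cv <- function(x, ...) {
  cat(sprintf(
    "Cross-validated model: outcome=%s predictors=%s (%dx%d-fold)\n",
    x$config$outcome, x$config$predictors, x$config$repeats, x$config$k))
  cat(sprintf("  pooled R^2 = %.4f  pooled NRMSE = %.4f\n",
              x$pooled_r2, x$pooled_nrmse))
  cat(sprintf("  per-fold R^2: median %.3f [%.3f, %.3f]\n",
              stats::median(x$fold_r2, na.rm = TRUE),
              min(x$fold_r2, na.rm = TRUE), max(x$fold_r2, na.rm = TRUE)))
  invisible(x)
}

#' Count train/test row-id overlap in the fit-event audit log
#'
#' The leakage guard: for every fit event recorded during a fold, counts
#' ids that also appear in that fold's test set. Must be zero by
#' construction.
#'
#' @param cv_result a `symdim_cv` (or `symdim_loso` element) with an audit.
#' @return total number of overlapping ids across all fit events.
#' @export
audit_leakage <- function(cv_result) {
  audit <- cv_result$audit
  if (is.null(audit)) stop("audit_leakage: no audit log present")
  total <- 0L
  fold_i <- 0L
  events_per_fold <- length(audit$events) / length(audit$test_ids)
  for (i in seq_along(audit$test_ids)) {
    test <- audit$test_ids[[i]]
    from <- floor((i - 1) * events_per_fold) + 1L
    to <- floor(i * events_per_fold)
    for (j in from:to)
      total <- total + length(intersect(audit$events[[j]]$train_ids, test))
  }
  total
}

#' Leave-one-site-out cross-validation
#'
#' For each site: fit transforms and the ensemble on the remaining sites,
#' then predict the held-out site. Because the held-out site contributed no
#' harmonization parameters, its subjects are (when `use_pseudo_site =
#' TRUE`) assigned pseudo-site labels by a site classifier trained on the
#' training features, and harmonized as if from those sites. With
#' `use_pseudo_site = FALSE` and `harmonize = TRUE` the run fails by
#' design, demonstrating why the approximation exists.
#'
#' @inheritParams run_cv
#' @param use_pseudo_site assign training-site pseudo-labels to held-out
#'   subjects before harmonization.
#' @return object of class `symdim_loso`: one result per held-out site
#'   (`site`, `r2`, `nrmse`, `predictions`), plus pooled audit.
#' @export
run_loso <- function(cohort, outcome, predictors = c("full", "imaging_only"),
                     use_pseudo_site = TRUE, num_trees = 1000L, mtry = NULL,
                     seed = 1L, harmonize = TRUE,
                     harmonize_method = "empirical_bayes",
                     residualize = TRUE, outcome_values = NULL) {
  predictors <- match.arg(predictors)
  sites <- sort(unique(cohort$site))
  if (length(sites) < 3L) stop("run_loso: need >= 3 sites")
  col <- outcome_column(outcome)
  scored <- score_cohort(cohort)
  y <- if (is.null(outcome_values)) scored$change[[col]] else
    as.numeric(outcome_values)
  baseline_sev <- scored$baseline[[col]]
  fold_seeds <- withr::with_seed(as.integer(seed),
                                 sample.int(.Machine$integer.max,
                                            length(sites)))
  audit <- new.env(parent = emptyenv())
  audit$events <- list()
  results <- list()
  test_ids <- list()
  for (i in seq_along(sites)) {
    s <- sites[i]
    te <- which(cohort$site == s)
    tr <- which(cohort$site != s)
    # held-out site indicators are all-zero columns in training: drop site
    # from the predictor set under LOSO (its level cannot be learned)
    res <- fit_fold(cohort, y, baseline_sev, tr, te, predictors,
                    residualize, harmonize, harmonize_method, num_trees,
                    mtry, fold_seeds[i], audit,
                    site_levels = setdiff(sites, s),
                    pseudo_site = use_pseudo_site)
    predictions <- data.frame(id = cohort$id[te], site = s, actual = y[te],
                              predicted = res$pred, stringsAsFactors = FALSE)
    results[[s]] <- list(
      site = s,
      r2 = if (stats::var(y[te]) > 0) r_squared(y[te], res$pred) else NA_real_,
      nrmse = if (max(y[te]) > min(y[te])) nrmse(y[te], res$pred) else
        NA_real_,
      predictions = predictions)
    test_ids[[i]] <- cohort$id[te]
  }
  structure(list(sites = results,
                 audit = list(events = audit$events, test_ids = test_ids),
                 config = list(outcome = outcome, predictors = predictors,
                               use_pseudo_site = use_pseudo_site,
                               harmonize = harmonize, seed = seed,
                               num_trees = num_trees)),
            class = "symdim_loso")
}

#' @export
print.symdim_loso <- function(x, ...) {
  cat(sprintf("Leave-one-site-out results (outcome=%s, pseudo-site=%s):\n",
              x$config$outcome, x$config$use_pseudo_site))
  for (r in x$sites)
    cat(sprintf("  held-out %s: R^2 = %.4f, NRMSE = %.4f\n",
                r$site, r$r2, r$nrmse))
  invisible(x)
}
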
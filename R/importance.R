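# Permutation-based model interrogation: feature importance as percent
# increase in mean squared error (PIMSE), median-conditioned partial
# dependence profiles, permutation-null significance of cross-validated
# fits, and cross-factor specificity checks.

#' Permutation importance: percent increase in MSE
#'
#' For each feature, its column in the evaluation matrix is shuffled
#' `n_permutations` times; PIMSE is `100 * (mean permuted MSE - baseline
#' MSE) / baseline MSE`. A feature the ensemble never uses gets exactly 0;
#' negative values (shuffling helped by chance) are reported as-is. Ranks
#' order by decreasing PIMSE with ties broken by feature name order.
#'
#' @param fit a `symdim_rf` regression fit.
#' @param features evaluation feature matrix (test folds, or the training
#'   matrix with `oob = TRUE`).
#' @param actual outcome values for the evaluation rows.
#' @param n_permutations shuffles per feature (default 10).
#' @param seed optional integer seed.
#' @param oob use out-of-bag predictions (fit must keep inbag counts and
#'   `features` must be the training matrix).
#' @return data.frame with columns `feature`, `pimse`, `rank`.
#' @export
pimse_importance <- function(fit, features, actual, n_permutations = 10L,
                             seed = NULL, oob = FALSE) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(actual))
  run <- function() {
    base_pred <- predict(fit, features, oob = oob)
    ok <- !is.na(base_pred)
    mse_base <- mean((actual[ok] - base_pred[ok])^2)
    if (mse_base == 0)
      stop("pimse_importance: baseline MSE is zero")
    p <- ncol(features)
    nm <- colnames(features)
    if (is.null(nm)) nm <- paste0("x", seq_len(p))
    pimse <- numeric(p)
    n <- nrow(features)
    for (j in seq_len(p)) {
      mses <- numeric(n_permutations)
      shuffled <- features
      for (b in seq_len(n_permutations)) {
        shuffled[, j] <- features[sample.int(n), j]
        pred <- predict(fit, shuffled, oob = oob)
        mses[b] <- mean((actual[ok] - pred[ok])^2)
      }
      pimse[j] <- 100 * (mean(mses) - mse_base) / mse_base
    }
    ord <- order(-pimse, nm)
    rank <- integer(p)
    rank[ord] <- seq_len(p)
    data.frame(feature = nm, pimse = pimse, rank = rank,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Partial dependence profile of one feature
#'
#' Default convention: the model's expected outcome over a grid of the
#' feature's observed-range quantiles while *all other predictors are held
#' at their observed median values* (a median-conditioned profile). The
#' conventional marginal-average partial dependence is available with
#' `convention = "marginal"`.
#'
#' @param fit a `symdim_rf` regression fit.
#' @param features feature matrix defining the observed distribution.
#' @param feature_name column to profile.
#' @param n_grid number of grid points (>= 2).
#' @param convention `"median"` (default) or `"marginal"`.
#' @return list of class `symdim_pdp`: `feature_name`, `grid_values`
#'   (strictly increasing), `expected_outcome`, `others_held_at`.
#' @export
partial_dependence <- function(fit, features, feature_name, n_grid = 20L,
                               convention = c("median", "marginal")) {
  convention <- match.arg(convention)
  features <- as.matrix(features)
  if (!feature_name %in% colnames(features))
    stop("partial_dependence: unknown feature '", feature_name, "'")
  stopifnot(n_grid >= 2L)
  x <- features[, feature_name]
  grid <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_grid),
                                 names = FALSE, type = 7))
  if (length(grid) == 1L)
    warning("partial_dependence: feature '", feature_name,
            "' is constant; single-point grid")
  if (convention == "median") {
    med <- apply(features, 2, stats::median)
    newdata <- matrix(med, nrow = length(grid), ncol = ncol(features),
                      byrow = TRUE, dimnames = list(NULL, colnames(features)))
    newdata[, feature_name] <- grid
    expected <- predict(fit, newdata)
  } else {
    expected <- vapply(grid, function(g) {
      nd <- features
      nd[, feature_name] <- g
      mean(predict(fit, nd))
    }, numeric(1))
  }
  structure(list(feature_name = feature_name, grid_values = grid,
                 expected_outcome = as.numeric(expected),
                 others_held_at = if (convention == "median") "median" else
                   "marginal"),
            class = "symdim_pdp")
}

#' Permutation-null significance of a cross-validated model
#'
#' The outcome vector is permuted across subjects `n_shuffles` times and
#' the *entire* cross-validation pipeline (transforms and all) is re-run on
#' each shuffled outcome, giving a null distribution of pooled R-squared.
#' The p-value uses the add-one estimator `p = (1 + #\{null >= observed\}) /
#' (1 + n_shuffles)`, so the smallest attainable p with 100 shuffles is
#' 1/101 < .01.
#'
#' @param cv_runner callable `function(cohort, outcome, outcome_values)`
#'   returning an object with element `pooled_r2` (see [make_cv_runner()]).
#' @param cohort cohort data.frame.
#' @param outcome outcome name (see [run_cv()]).
#' @param n_shuffles number of permutations (primary-analysis setting: 100).
#' @param seed integer seed for the shuffles.
#' @return list with `observed_r2`, `null_r2` (length `n_shuffles`),
#'   `p_value`.
#' @export
permutation_test <- function(cv_runner, cohort, outcome, n_shuffles = 100L,
                             seed = 1L) {
  stopifnot(n_shuffles >= 1L)
  observed <- cv_runner(cohort, outcome, NULL)$pooled_r2
  y <- score_cohort(cohort)$change[[outcome_column(outcome)]]
  null_r2 <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_shuffles), function(s) {
      cv_runner(cohort, outcome, sample(y))$pooled_r2
    }, numeric(1))
  })
  list(observed_r2 = observed, null_r2 = null_r2,
       p_value = permutation_p(observed, null_r2))
}

#' Add-one permutation p-value from a null sample
#'
#' @param observed observed statistic.
#' @param null_values vector of null statistics.
#' @return `(1 + #\{null >= observed\}) / (1 + length(null_values))`.
#' @export
permutation_p <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Convenience factory for permutation-test CV runners
#'
#' @param ... fixed arguments forwarded to [run_cv()] (`k`, `repeats`,
#'   `num_trees`, `predictors`, `seed`, ...).
#' @return `function(cohort, outcome, outcome_values)` suitable for
#'   [permutation_test()].
#' @export
make_cv_runner <- function(...) {
  fixed <- list(...)
  function(cohort, outcome, outcome_values = NULL) {
    do.call(run_cv, c(list(cohort = cohort, outcome = outcome,
                           outcome_values = outcome_values), fixed))
  }
}

#' Score a fitted cross-validation result against another outcome
#'
#' Cross-factor specificity: the per-fold test predictions of a model
#' trained on outcome A are scored against outcome B's actual changes
#' (same subjects, same fold plans). With A = B this reproduces the
#' original result.
#'
#' @param cv_result a `symdim_cv` trained on some outcome.
#' @param cohort the cohort the result was computed on.
#' @param outcome_b outcome whose actual changes to score against.
#' @return list with `pooled_r2`, `repeat_r2`, `outcome_trained`,
#'   `outcome_evaluated`.
#' @export
cross_factor_predict <- function(cv_result, cohort, outcome_b) {
  stopifnot(inherits(cv_result, "symdim_cv"))
  y_b <- score_cohort(cohort)$change[[outcome_column(outcome_b)]]
  names(y_b) <- cohort$id
  preds <- cv_result$predictions
  if (!all(preds$id %in% cohort$id))
    stop("cross_factor_predict: prediction ids not found in cohort ",
         "(mismatched fold plans?)")
  preds$actual <- y_b[preds$id]
  by_rep <- split(preds, preds$rep)
  repeat_r2 <- vapply(by_rep, function(d) r_squared(d$actual, d$predicted),
                      numeric(1))
  list(pooled_r2 = mean(repeat_r2), repeat_r2 = unname(repeat_r2),
       outcome_trained = cv_result$config$outcome,
       outcome_evaluated = outcome_b)
}
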
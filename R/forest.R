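#' Bagged regression-tree ensemble
#'
#' Fits a random forest regressor: `num_trees` CART trees grown on bootstrap
#' resamples of the training data, each split chosen among `mtry` randomly
#' drawn candidate features by maximal reduction in residual sum of squares
#' (i.e. the trees minimize RMSE). Predictions average the trees. This is the
#' learner used throughout the cross-validation engine.
#'
#' @param x numeric feature matrix (subjects x features); column names are
#'   retained and enforced at prediction time.
#' @param y numeric outcome vector, `length(y) == nrow(x)`.
#' @param num_trees number of trees (the main analysis uses 1,000).
#' @param mtry candidate features per split; default `max(floor(p/3), 1)`.
#' @param min_node minimal node size eligible for splitting (default 5).
#' @param keep_inbag keep per-tree bootstrap counts, enabling out-of-bag
#'   prediction via [predict.symdim_rf()] with `oob = TRUE`.
#' @param seed optional integer; when given the fit is reproducible
#'   irrespective of the caller's RNG state.
#' @return an object of class `symdim_rf`.
#' @export
rf_regression <- function(x, y, num_trees = 1000L, mtry = NULL,
                          min_node = 5L, keep_inbag = FALSE, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  if (anyNA(x) || anyNA(y)) stop("rf_regression: missing values in x or y")
  if (is.null(mtry)) mtry <- max(floor(ncol(x) / 3), 1L)
  fit_fun <- function() {
    .rf_grow(x, y, as.integer(num_trees), as.integer(mtry),
             as.integer(max(min_node, 2L)), 0L, keep_inbag)
  }
  raw <- if (is.null(seed)) fit_fun() else withr::with_seed(seed, fit_fun())
  structure(
    list(trees = raw$trees,
         inbag = if (keep_inbag) raw$inbag else NULL,
         feature_names = colnames(x),
         type = "regression",
         num_trees = as.integer(num_trees), mtry = as.integer(mtry),
         n_train = nrow(x)),
    class = "symdim_rf")
}

#' Bagged classification-tree ensemble
#'
#' Majority-vote random forest classifier (Gini splits); used as the
#' intermediary model that assigns pseudo-site labels to held-out-site
#' subjects in leave-one-site-out validation.
#'
#' @inheritParams rf_regression
#' @param y factor (or coercible) of class labels.
#' @param min_node minimal node size eligible for splitting (default 2).
#' @export
rf_classification <- function(x, y, num_trees = 500L, mtry = NULL,
                              min_node = 2L, keep_inbag = FALSE, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  if (anyNA(x) || anyNA(y)) stop("rf_classification: missing values in x or y")
  if (is.null(mtry)) mtry <- max(floor(sqrt(ncol(x))), 1L)
  y_idx <- as.numeric(as.integer(y) - 1L)
  fit_fun <- function() {
    .rf_grow(x, y_idx, as.integer(num_trees), as.integer(mtry),
             as.integer(max(min_node, 2L)), nlevels(y), keep_inbag)
  }
  raw <- if (is.null(seed)) fit_fun() else withr::with_seed(seed, fit_fun())
  structure(
    list(trees = raw$trees,
         inbag = if (keep_inbag) raw$inbag else NULL,
         feature_names = colnames(x),
         type = "classification", levels = levels(y),
         num_trees = as.integer(num_trees), mtry = as.integer(mtry),
         n_train = nrow(x)),
    class = "symdim_rf")
}

#' Predict from a fitted forest
#'
#' @param object a `symdim_rf` fit.
#' @param newdata numeric matrix with the training feature columns (matched
#'   by name when both are named).
#' @param oob logical; if `TRUE`, return out-of-bag predictions. `newdata`
#'   must then be the training matrix of a fit made with `keep_inbag = TRUE`.
#' @param ... unused.
#' @return numeric vector (regression) or factor (classification).
#' @export
predict.symdim_rf <- function(object, newdata, oob = FALSE, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing) > 0)
      stop("predict.symdim_rf: newdata lacks feature(s): ",
           paste(missing, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  if (oob) {
    if (is.null(object$inbag))
      stop("predict.symdim_rf: fit was made without keep_inbag = TRUE")
    if (nrow(newdata) != nrow(object$inbag))
      stop("predict.symdim_rf: oob prediction requires the training matrix")
    if (object$type != "regression")
      stop("predict.symdim_rf: oob prediction implemented for regression only")
    return(.rf_predict_reg_oob(object$trees, newdata, object$inbag))
  }
  if (object$type == "regression") {
    .rf_predict_reg(object$trees, newdata)
  } else {
    idx <- .rf_predict_class(object$trees, newdata, length(object$levels))
    factor(object$levels[idx], levels = object$levels)
  }
}
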
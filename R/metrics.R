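#' Sum-of-squares coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, the fraction of
#' outcome variance explained by the predictions. Unbounded below: values
#' less than 0 mean the model predicts worse than the outcome mean and are
#' reported as-is, never clamped.
#'
#' @param actual,predicted numeric vectors of equal length (>= 2).
#' @return a single numeric value.
#' @export
r_squared <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2L)
  if (anyNA(actual) || anyNA(predicted)) stop("r_squared: missing values")
  sstot <- sum((actual - mean(actual))^2)
  if (sstot == 0)
    stop("r_squared: actual values are constant (undefined denominator)")
  1 - sum((actual - predicted)^2) / sstot
}

#' Normalized root-mean-squared error
#'
#' RMSE divided by the observed outcome range `max(actual) - min(actual)`
#' of the evaluated set, making errors comparable across scales with
#' different ranges.
#'
#' @inheritParams r_squared
#' @return a single non-negative numeric value.
#' @export
nrmse <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2L)
  if (anyNA(actual) || anyNA(predicted)) stop("nrmse: missing values")
  rng <- max(actual) - min(actual)
  if (rng == 0) stop("nrmse: zero outcome range in evaluated set")
  sqrt(mean((actual - predicted)^2)) / rng
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure at level `q`: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, reject hypotheses `1..k*` where `k*` is the largest `k` with
#' `p_(k) <= k q / m`. Adjusted p-values are the usual step-up minima.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q significance level (default 0.05).
#' @return list with logical `reject` and numeric `p_adjusted`, both in the
#'   input order.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("fdr_adjust: p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o]
  # adjusted p: running minimum from the largest rank down
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj <- pmin(adj, 1)
  passing <- which(ranked <= seq_len(m) * q / m)
  k_star <- if (length(passing) > 0) max(passing) else 0L
  reject <- logical(m)
  if (k_star > 0) reject[o[seq_len(k_star)]] <- TRUE
  p_adjusted <- numeric(m)
  p_adjusted[o] <- adj
  list(reject = reject, p_adjusted = p_adjusted)
}

#' One-way ANOVA on cross-validation score samples
#'
#' Fixed-effects one-way ANOVA comparing two or more groups of per-fold
#' R-squared values (e.g. models for different symptom dimensions). Fold
#' scores from a common resampling scheme are not strictly independent, so
#' the p-value is approximate in the usual way this comparison is run.
#'
#' @param ... two or more numeric vectors (each length >= 2), or a single
#'   list of such vectors.
#' @return list with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
compare_models <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2L) stop("compare_models: need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("compare_models: every group needs >= 2 values")
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  grand <- mean(x)
  means <- tapply(x, g, mean)
  n_g <- tapply(x, g, length)
  ss_between <- sum(n_g * (means - grand)^2)
  ss_within <- sum((x - means[g])^2)
  df_b <- length(groups) - 1L
  df_w <- length(x) - length(groups)
  if (df_w <= 0) stop("compare_models: degenerate groups")
  if (ss_within == 0) {
    f <- if (ss_between == 0) 0 else Inf
  } else {
    f <- (ss_between / df_b) / (ss_within / df_w)
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  list(f_statistic = f, p_value = p, df_between = df_b, df_within = df_w)
}
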
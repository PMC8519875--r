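# Fold-contained preprocessing transforms. Everything here follows a strict
# fit/apply split: fit_* functions look only at training rows and return a
# parameter object; apply_* functions are deterministic in those parameters.

#' Fit a covariate encoder/imputer on training data
#'
#' Numeric covariates are imputed with the training median; categorical
#' covariates (character/factor/logical) with the training mode, and then
#' expanded into indicator columns with the most frequent training level as
#' the reference. Parameters are frozen so the identical mapping is applied
#' to test rows.
#'
#' @param df data.frame of covariates (training rows only).
#' @return an object of class `symdim_encoder`.
#' @export
encoder_fit <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  cols <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      med <- stats::median(x, na.rm = TRUE)
      if (is.na(med)) stop("encoder_fit: column '", nm, "' entirely missing")
      list(name = nm, kind = "numeric", impute = med)
    } else {
      x <- as.character(x)
      tab <- sort(table(x[!is.na(x)]), decreasing = TRUE)
      if (length(tab) == 0)
        stop("encoder_fit: column '", nm, "' entirely missing")
      lv <- names(tab)  # most frequent first => reference level
      list(name = nm, kind = "categorical", impute = lv[1],
           levels = lv, reference = lv[1])
    }
  })
  structure(list(columns = cols, fitted_on_n = nrow(df)),
            class = "symdim_encoder")
}

#' Apply a fitted encoder
#'
#' @param encoder a `symdim_encoder` from [encoder_fit()].
#' @param df data.frame with the same covariate columns.
#' @param strict_levels error on a categorical level unseen in training
#'   (default TRUE); if FALSE the unseen level maps to the reference.
#' @return numeric design matrix (no intercept column).
#' @export
encoder_apply <- function(encoder, df, strict_levels = TRUE) {
  stopifnot(inherits(encoder, "symdim_encoder"))
  out <- list()
  for (col in encoder$columns) {
    if (!col$name %in% names(df))
      stop("encoder_apply: missing covariate column '", col$name, "'")
    x <- df[[col$name]]
    if (col$kind == "numeric") {
      x <- as.numeric(x)
      x[is.na(x)] <- col$impute
      out[[col$name]] <- x
    } else {
      x <- as.character(x)
      x[is.na(x)] <- col$impute
      unseen <- setdiff(unique(x), col$levels)
      if (length(unseen) > 0) {
        if (strict_levels)
          stop("encoder_apply: unseen level(s) in '", col$name, "': ",
               paste(unseen, collapse = ", "))
        x[x %in% unseen] <- col$reference
      }
      for (lv in setdiff(col$levels, col$reference))
        out[[paste0(col$name, "_", lv)]] <- as.numeric(x == lv)
    }
  }
  mat <- do.call(cbind, out)
  rownames(mat) <- rownames(df)
  mat
}

#' Fit per-feature confound regressions on training data
#'
#' Ordinary least squares of each imaging feature on the covariate design
#' (with intercept). The stored coefficients reproduce the training fitted
#' values exactly and are later applied unchanged to test data, so no test
#' information can influence the residualization.
#'
#' @param features numeric matrix (subjects x features).
#' @param covariates numeric design matrix (subjects x covariates), no
#'   intercept column (one is added internally).
#' @return an object of class `symdim_residualization` with elements
#'   `covariate_names`, `betas` ((1 + n_cov) x n_features), `fitted_on_n`.
#' @export
residualize_fit <- function(features, covariates) {
  features <- as.matrix(features)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(features) == nrow(covariates))
  if (anyNA(features) || anyNA(covariates))
    stop("residualize_fit: missing values (impute first)")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  # constant columns are absorbed by the intercept (beta 0); a genuine
  # linear dependency among the remaining columns is an error
  is_const <- apply(covariates, 2, function(v) max(v) == min(v))
  active <- covariates[, !is_const, drop = FALSE]
  design <- cbind(`(intercept)` = 1, active)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("residualize_fit: rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  betas_active <- qr.coef(qr_d, features)
  betas <- matrix(0, nrow = 1 + ncol(covariates), ncol = ncol(features),
                  dimnames = list(c("(intercept)", colnames(covariates)),
                                  colnames(features)))
  betas[rownames(betas_active), ] <- betas_active
  structure(list(covariate_names = colnames(covariates), betas = betas,
                 fitted_on_n = nrow(features)),
            class = "symdim_residualization")
}

#' Residualize features using stored training parameters
#'
#' Returns `features - [1, covariates] %*% betas`; never refits.
#'
#' @param params a `symdim_residualization` from [residualize_fit()].
#' @param features,covariates matrices for the rows to transform; covariate
#'   columns must match `params$covariate_names`.
#' @return residual matrix with the dimensions of `features`.
#' @export
residualize_apply <- function(params, features, covariates) {
  stopifnot(inherits(params, "symdim_residualization"))
  features <- as.matrix(features)
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  missing <- setdiff(params$covariate_names, colnames(covariates))
  if (length(missing) > 0)
    stop("residualize_apply: missing covariate(s): ",
         paste(missing, collapse = ", "))
  covariates <- covariates[, params$covariate_names, drop = FALSE]
  design <- cbind(1, covariates)
  features - design %*% params$betas
}

#' Pseudo-site labels for held-out-site subjects
#'
#' Trains an ensemble of classification trees to predict acquisition site
#' from training features, then assigns each held-out subject the training
#' site its features most resemble. This makes batch harmonization
#' applicable to data from a site that contributed nothing to the training
#' parameters (leave-one-site-out validation).
#'
#' @param train_features,heldout_features numeric matrices with identical
#'   columns.
#' @param train_site_labels site label per training row.
#' @param num_trees trees in the site classifier (default 500).
#' @param seed optional integer for reproducibility.
#' @return factor of training-site labels, one per held-out row.
#' @export
pseudo_site_labels <- function(train_features, train_site_labels,
                               heldout_features, num_trees = 500L,
                               seed = NULL) {
  train_site_labels <- factor(train_site_labels)
  if (nlevels(train_site_labels) < 2L) {
    warning("pseudo_site_labels: single training site; all held-out ",
            "subjects assigned to it")
    return(factor(rep(levels(train_site_labels), nrow(heldout_features)),
                  levels = levels(train_site_labels)))
  }
  fit <- rf_classification(train_features, train_site_labels,
                           num_trees = num_trees, seed = seed)
  predict(fit, heldout_features)
}
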
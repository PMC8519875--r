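# Cohort table I/O with validation, fitted-transform serialization, and
# the end-to-end pipeline runner.

cohort_fixed_cols <- c("id", "site", "age", "sex", "bmi",
                       "electrode_primary", "electrode_secondary")

#' Write a cohort table (and optional generator truth) to disk
#'
#' @param cohort cohort data.frame.
#' @param path CSV output path.
#' @param truth optional `synthetic_truth`; written as JSON next to the
#'   CSV (same basename, `.truth.json`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE)
  if (!is.null(truth)) {
    tp <- sub("\\.csv$", "", path)
    write_truth(truth, paste0(tp, ".truth.json"))
  }
  invisible(path)
}

#' Serialize generator ground truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  out <- unclass(truth)
  out$config <- unclass(out$config)
  out$true_volumes <- NULL  # bulky; reproducible from the config seed
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Checks the schema written by [write_cohort()]: unique non-empty subject
#' ids, non-empty site labels, numeric region columns, and HDRS items
#' within their legal ranges. Violations are reported with row and column
#' coordinates.
#'
#' @param path CSV path.
#' @param schema_version accepted schema version (currently `1`).
#' @return validated cohort data.frame with attributes `region_names` and
#'   `provenance` (source file and md5 checksum).
#' @export
read_cohort <- function(path, schema_version = 1L) {
  stopifnot(schema_version == 1L)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  need <- c(cohort_fixed_cols, sprintf("hdrs_pre_%02d", 1:17),
            sprintf("hdrs_post_%02d", 1:17))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("read_cohort: missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id))
    add(paste("duplicate subject id(s):",
              paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  if (any(is.na(df$site) | df$site == ""))
    add(paste("empty site label at row(s):",
              paste(which(is.na(df$site) | df$site == ""), collapse = ", ")))
  for (ph in c("pre", "post")) {
    for (j in 1:17) {
      colnm <- sprintf("hdrs_%s_%02d", ph, j)
      v <- df[[colnm]]
      bad <- which(!is.na(v) & (v < 0 | v > hdrs_items$max[j] |
                                  v != round(v)))
      if (length(bad) > 0)
        add(sprintf("item %s (%s) out of range [0,%d] at row(s) %s",
                    hdrs_items$name[j], colnm, hdrs_items$max[j],
                    paste(bad, collapse = ", ")))
    }
  }
  region_cols <- grep("^vol_change_", names(df), value = TRUE)
  for (colnm in region_cols) {
    if (!is.numeric(df[[colnm]]))
      add(sprintf("region column %s is not numeric", colnm))
  }
  extra <- setdiff(names(df), c(need, "psychotic", region_cols))
  if (length(extra) > 0)
    add(paste("unknown column(s):", paste(extra, collapse = ", ")))
  if (length(problems) > 0)
    stop("read_cohort: validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  if (is.null(df$psychotic)) df$psychotic <- FALSE
  df$psychotic <- as.logical(df$psychotic)
  attr(df, "region_names") <- sub("^vol_change_", "", region_cols)
  attr(df, "provenance") <- list(source = normalizePath(path),
                                 md5 = unname(tools::md5sum(path)))
  df
}

#' Serialize a fitted transform to versioned JSON
#'
#' Makes fold-fitted residualization or harmonization parameters portable
#' across runs: [read_transform()] restores an object that applies
#' identically.
#'
#' @param params a `symdim_residualization` or `symdim_harmonization`.
#' @param path output path.
#' @export
write_transform <- function(params, path) {
  kind <- class(params)[1]
  stopifnot(kind %in% c("symdim_residualization", "symdim_harmonization"))
  payload <- unclass(params)
  payload$adjusted <- NULL
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(
    list(schema = "symdim_transform", version = 1L, kind = kind,
         params = payload),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Restore a fitted transform written by [write_transform()]
#' @param path JSON path.
#' @return the transform object.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "symdim_transform"))
    stop("read_transform: not a symdim transform file")
  p <- obj$params
  if (obj$kind == "symdim_residualization") {
    p$betas <- as.matrix(p$betas)
    rownames(p$betas) <- c("(intercept)", p$covariate_names)
  } else {
    for (nm in c("gamma_hat", "delta_hat", "gamma_star", "delta_star")) {
      p[[nm]] <- as.matrix(p[[nm]])
      dimnames(p[[nm]]) <- list(p$sites, p$feature_names)
    }
    p$grand_mean <- as.numeric(p$grand_mean)
    p$var_pooled <- as.numeric(p$var_pooled)
    if (length(p$cov_coefs) == 0) p$cov_coefs <- NULL
    else p$cov_coefs <- as.matrix(p$cov_coefs)
  }
  class(p) <- obj$kind
  p
}

default_pipeline_config <- function() {
  list(cohort_csv = NULL, outcomes = outcome_names, predictors = "full",
       k = 10L, repeats = 10L, num_trees = 1000L, n_shuffles = 0L,
       q = 0.05, exclude_site = NULL, exclude_psychotic = FALSE,
       loso = FALSE, pseudo_site = TRUE, importance = TRUE,
       n_importance_shuffles = 10L, pdp_top = 6L, pdp_grid = 20L,
       seed = 1L)
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate-or-read, dimension scoring, cross-validation (or
#' leave-one-site-out), optional permutation tests with FDR adjustment
#' across outcomes, and full-data permutation importance plus partial
#' dependence grids. All artifacts (manifest, metrics JSON, predictions /
#' importance / PDP CSVs, fit-event log) are written under `out_dir`; a
#' stage marker records the failing stage if any step errors.
#'
#' @param config a named list or path to a flat YAML file; unset keys take
#'   defaults mirroring the primary analysis (k = 10, repeats = 10,
#'   num_trees = 1000, q = 0.05; `n_shuffles` defaults to 0 -- set 100 for
#'   the full permutation test).
#' @param out_dir artifact directory (created if needed).
#' @return invisibly, a list with per-outcome results and artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  mark_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    stage <- "load"
    if (is.null(cfg$cohort_csv)) {
      gen <- generate_cohort(cohort_config(seed = cfg$seed))
      cohort <- gen$subjects
      write_cohort(cohort, file.path(out_dir, "cohort.csv"), gen$truth)
    } else {
      cohort <- read_cohort(cfg$cohort_csv)
    }
    if (!is.null(cfg$exclude_site))
      cohort <- cohort[!cohort$site %in% cfg$exclude_site, , drop = FALSE]
    if (isTRUE(cfg$exclude_psychotic))
      cohort <- cohort[!cohort$psychotic, , drop = FALSE]
    stage <- "score"
    scored <- score_cohort(cohort)
    metrics <- list(n_subjects = nrow(cohort),
                    sites = table(cohort$site), outcomes = list())
    results <- list()
    all_preds <- list()
    stage <- "cross_validation"
    for (oc in cfg$outcomes) {
      if (isTRUE(cfg$loso)) {
        res <- run_loso(cohort, oc, predictors = cfg$predictors,
                        use_pseudo_site = cfg$pseudo_site,
                        num_trees = cfg$num_trees, seed = cfg$seed)
        metrics$outcomes[[oc]] <- list(
          per_site = lapply(res$sites, function(r)
            list(site = r$site, r2 = r$r2, nrmse = r$nrmse)))
        all_preds[[oc]] <- do.call(rbind, lapply(res$sites, function(r)
          cbind(outcome = oc, r$predictions)))
      } else {
        res <- run_cv(cohort, oc, predictors = cfg$predictors, k = cfg$k,
                      repeats = cfg$repeats, num_trees = cfg$num_trees,
                      seed = cfg$seed)
        metrics$outcomes[[oc]] <- list(
          pooled_r2 = res$pooled_r2, pooled_nrmse = res$pooled_nrmse,
          repeat_r2 = res$repeat_r2,
          fold_r2_median = stats::median(res$fold_r2, na.rm = TRUE))
        all_preds[[oc]] <- cbind(outcome = oc, res$predictions)
      }
      results[[oc]] <- res
    }
    stage <- "permutation_test"
    if (cfg$n_shuffles > 0 && !isTRUE(cfg$loso)) {
      runner <- make_cv_runner(predictors = cfg$predictors, k = cfg$k,
                               repeats = cfg$repeats,
                               num_trees = cfg$num_trees, seed = cfg$seed)
      pvals <- vapply(cfg$outcomes, function(oc) {
        pt <- permutation_test(runner, cohort, oc,
                               n_shuffles = cfg$n_shuffles,
                               seed = cfg$seed)
        metrics$outcomes[[oc]]$p_value <<- pt$p_value
        pt$p_value
      }, numeric(1))
      adj <- fdr_adjust(pvals, q = cfg$q)
      for (i in seq_along(cfg$outcomes)) {
        metrics$outcomes[[cfg$outcomes[i]]]$p_fdr <- adj$p_adjusted[i]
        metrics$outcomes[[cfg$outcomes[i]]]$significant <- adj$reject[i]
      }
    }
    stage <- "importance"
    if (isTRUE(cfg$importance) && !isTRUE(cfg$loso)) {
      imp_rows <- list()
      pdp_rows <- list()
      for (oc in cfg$outcomes) {
        full <- full_data_fit(cohort, oc, predictors = cfg$predictors,
                              num_trees = cfg$num_trees, seed = cfg$seed)
        imp <- pimse_importance(full$fit, full$x, full$y,
                                n_permutations = cfg$n_importance_shuffles,
                                seed = cfg$seed, oob = TRUE)
        imp_rows[[oc]] <- cbind(outcome = oc, imp)
        top <- imp$feature[order(imp$rank)][seq_len(min(cfg$pdp_top,
                                                        nrow(imp)))]
        for (f in top) {
          grid <- partial_dependence(full$fit, full$x, f,
                                     n_grid = cfg$pdp_grid)
          pdp_rows[[paste(oc, f)]] <- data.frame(
            outcome = oc, feature = f, grid_value = grid$grid_values,
            expected_outcome = grid$expected_outcome)
        }
      }
      utils::write.csv(do.call(rbind, imp_rows),
                       file.path(out_dir, "importance.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, pdp_rows),
                       file.path(out_dir, "pdp.csv"), row.names = FALSE)
    }
    stage <- "write_artifacts"
    utils::write.csv(do.call(rbind, all_preds),
                     file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    manifest <- list(package = "symdim",
                     version = as.character(utils::packageVersion("symdim")),
                     config = cfg)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    # fit-event log: one record per transform/model fit with training n
    log_lines <- character(0)
    for (oc in names(results)) {
      ev <- results[[oc]]$audit$events
      log_lines <- c(log_lines, vapply(seq_along(ev), function(i)
        sprintf("outcome=%s fit=%d stage=%s n_train=%d", oc, i,
                ev[[i]]$stage, ev[[i]]$n), character(1)))
    }
    writeLines(log_lines, file.path(out_dir, "fit_log.txt"))
    invisible(list(results = results, metrics = metrics,
                   out_dir = out_dir))
  }, error = mark_fail)
}

# Fit the transform chain and ensemble on the complete cohort (no held-out
# data); used for cohort-level importance and partial dependence, with
# out-of-bag evaluation standing in for an independent test set.
full_data_fit <- function(cohort, outcome,
                          predictors = c("full", "imaging_only"),
                          num_trees = 1000L, seed = 1L,
                          harmonize = TRUE, residualize = TRUE) {
  predictors <- match.arg(predictors)
  col <- outcome_column(outcome)
  scored <- score_cohort(cohort)
  y <- scored$change[[col]]
  audit <- new.env(parent = emptyenv())
  audit$events <- list()
  res <- fit_fold(cohort, y, scored$baseline[[col]],
                  tr = seq_len(nrow(cohort)), te = seq_len(nrow(cohort)),
                  predictors = predictors, residualize = residualize,
                  harmonize = harmonize,
                  harmonize_method = "empirical_bayes",
                  num_trees = num_trees, mtry = NULL, fold_seed = seed,
                  audit = audit, site_levels = sort(unique(cohort$site)))
  # refit with inbag bookkeeping for OOB evaluation
  fit <- rf_regression(res$x_tr, y, num_trees = num_trees,
                       keep_inbag = TRUE, seed = seed)
  list(fit = fit, x = res$x_tr, y = y)
}
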
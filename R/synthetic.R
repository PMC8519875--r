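# Synthetic multisite ECT cohort generator. Emulates the statistical
# structure the analysis pipeline assumes -- four sites of unequal size with
# site-dependent covariate distributions, additive/multiplicative site
# effects on regional volume-change features, and sparse planted effects of
# regions and covariates on correlated dimension-change outcomes -- together
# with the ground truth needed for parameter-recovery tests.

#' Configuration for a synthetic multisite cohort
#'
#' Defaults describe a 110-subject, 4-site cohort (27/39/16/28 subjects)
#' with 82 bilateral FreeSurfer-style regions, site-specific age/BMI/sex/
#' electrode distributions, and a planted signal in which pretreatment
#' severity is the strongest predictor of dimension change.
#'
#' @param n_per_site integer vector of site sizes.
#' @param n_regions number of volume-change features.
#' @param n_informative_regions regions per dimension carrying true signal.
#' @param covariate_effect_sizes named slopes (outcome units per covariate
#'   SD, on the SoD scale; other dimensions are scaled proportionally) for
#'   `age`, `sex`, `bmi`, `baseline_severity`.
#' @param region_effect_size absolute slope of each informative region
#'   (outcome units per feature SD, SoD scale).
#' @param site_shift_sd SD of the per-site, per-region additive batch
#'   shifts.
#' @param site_scale_range length-2 range of the per-site, per-region
#'   multiplicative batch scales (uniform).
#' @param noise_sd residual SD of the dimension changes (length 1 or 3).
#'   When `NULL` (default) it is calibrated from `planted_r2`.
#' @param planted_r2 target fraction of dimension-change variance
#'   attributable to the planted signal (site profile + covariates +
#'   regions). `0` removes all planted effects.
#' @param dim_change_corr 3x3 correlation matrix of the dimension-change
#'   residuals.
#' @param site_change_shift per-site offsets of mean symptom change on the
#'   HDRS-17 total scale (default mimics one poorly-responding site).
#' @param shared_informative_regions if `TRUE`, the three dimensions share
#'   one informative region set (and slope pattern) instead of each drawing
#'   its own -- used to emulate overlapping neural substrates.
#' @param baseline_mu,baseline_sd means/SDs of the baseline dimension
#'   scores (`sod`, `cma`, `insomnia`).
#' @param mean_change cohort-mean change per dimension (negative =
#'   improvement).
#' @param seed integer seed; the same config generates bit-identical
#'   cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_site = c(27L, 39L, 16L, 28L),
                          n_regions = 82L,
                          n_informative_regions = 5L,
                          covariate_effect_sizes = c(age = -0.6, sex = 0.2,
                                                     bmi = -0.3,
                                                     baseline_severity = -1.5),
                          region_effect_size = 0.4,
                          site_shift_sd = 0.3,
                          site_scale_range = c(0.8, 1.25),
                          noise_sd = NULL,
                          planted_r2 = 0.4,
                          dim_change_corr = matrix(c(1, 0.5, 0.5,
                                                     0.5, 1, 0.5,
                                                     0.5, 0.5, 1), 3, 3),
                          site_change_shift = c(8.7, -4.8, -2.5, 1.7),
                          shared_informative_regions = FALSE,
                          baseline_mu = c(sod = 11, cma = 7.5,
                                          insomnia = 3.8),
                          baseline_sd = c(sod = 3.5, cma = 2.5,
                                          insomnia = 1.3),
                          mean_change = c(sod = -5.5, cma = -5.0,
                                          insomnia = -2.0),
                          seed = NULL) {
  cfg <- list(
    n_per_site = as.integer(n_per_site),
    site_names = paste0("site", seq_along(n_per_site)),
    n_regions = as.integer(n_regions),
    n_informative_regions = as.integer(n_informative_regions),
    covariate_effect_sizes = covariate_effect_sizes,
    region_effect_size = region_effect_size,
    site_shift_sd = site_shift_sd,
    site_scale_range = site_scale_range,
    noise_sd = noise_sd,
    planted_r2 = planted_r2,
    dim_change_corr = dim_change_corr,
    site_change_shift = rep_len(site_change_shift, length(n_per_site)),
    shared_informative_regions = isTRUE(shared_informative_regions),
    # Site covariate profiles: age/BMI means per Table-1-like defaults,
    # recycled if the number of sites differs from four.
    site_age_mean = rep_len(c(40.9, 64.4, 52.1, 46.1), length(n_per_site)),
    site_age_sd = rep_len(c(14.7, 9.0, 10.8, 10.2), length(n_per_site)),
    site_bmi_mean = rep_len(c(25.5, 26.3, 23.6, 27.2), length(n_per_site)),
    bmi_sd = 5.3,
    female_prob = rep_len(c(13 / 27, 26 / 39, 11 / 16, 17 / 28),
                          length(n_per_site)),
    psychotic_prob = rep_len(c(0, 16 / 39, 3 / 16, 0), length(n_per_site)),
    site_baseline_shift = rep_len(c(-0.6, -0.5, 3.6, -2.7),
                                  length(n_per_site)),
    baseline_mu = baseline_mu,
    baseline_sd = baseline_sd,
    mean_change = mean_change,
    seed = seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Errors name the violated invariant.
#' @param config a `cohort_config`.
#' @return the config, invisibly.
#' @export
validate_cohort_config <- function(config) {
  fail <- function(msg) stop("invalid cohort config: ", msg, call. = FALSE)
  if (length(config$n_per_site) < 1L || any(config$n_per_site < 1L))
    fail("n_per_site must be positive integers")
  if (config$n_regions < 1L) fail("n_regions must be positive")
  if (config$n_informative_regions < 0L ||
      config$n_informative_regions > config$n_regions)
    fail("n_informative_regions must satisfy 0 <= k <= n_regions")
  cc <- config$dim_change_corr
  if (!is.matrix(cc) || any(dim(cc) != 3L))
    fail("dim_change_corr must be a 3x3 matrix")
  if (max(abs(cc - t(cc))) > 1e-8) fail("dim_change_corr must be symmetric")
  if (max(abs(diag(cc) - 1)) > 1e-8)
    fail("dim_change_corr must have unit diagonal")
  if (min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    fail("dim_change_corr must be positive semi-definite")
  sr <- config$site_scale_range
  if (length(sr) != 2L || any(sr <= 0) || sr[1] > sr[2])
    fail("site_scale_range must be 0 < lower <= upper")
  if (config$site_shift_sd < 0) fail("site_shift_sd must be non-negative")
  if (!is.null(config$noise_sd) && any(config$noise_sd <= 0))
    fail("noise_sd must be positive")
  if (is.null(config$noise_sd) &&
      (config$planted_r2 < 0 || config$planted_r2 >= 1))
    fail("planted_r2 must lie in [0, 1)")
  missing <- setdiff(c("age", "sex", "bmi", "baseline_severity"),
                     names(config$covariate_effect_sizes))
  if (length(missing) > 0)
    fail(paste("covariate_effect_sizes lacks", paste(missing, collapse = ", ")))
  invisible(config)
}

#' FreeSurfer-style region names
#'
#' 82 bilateral names (34 Desikan cortical + 7 subcortical structures per
#' hemisphere) when `n == 82`, generic `region_XX` otherwise.
#' @param n number of regions.
#' @return character vector of length `n`.
#' @export
region_names <- function(n = 82L) {
  cortical <- c("bankssts", "caudal_anterior_cingulate",
                "caudal_middle_frontal", "cuneus", "entorhinal", "fusiform",
                "inferior_parietal", "inferior_temporal", "isthmus_cingulate",
                "lateral_occipital", "lateral_orbitofrontal", "lingual",
                "medial_orbitofrontal", "middle_temporal", "parahippocampal",
                "paracentral", "pars_opercularis", "pars_orbitalis",
                "pars_triangularis", "pericalcarine", "postcentral",
                "posterior_cingulate", "precentral", "precuneus",
                "rostral_anterior_cingulate", "rostral_middle_frontal",
                "superior_frontal", "superior_parietal", "superior_temporal",
                "supramarginal", "frontal_pole", "temporal_pole",
                "transverse_temporal", "insula")
  subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                   "hippocampus", "amygdala", "accumbens")
  if (n == 82L) {
    as.vector(t(outer(c("lh", "rh"), c(cortical, subcortical), paste,
                      sep = "_")))
  } else {
    sprintf("region_%03d", seq_len(n))
  }
}

# Largest-remainder integer allocation of a dimension score across its
# items, proportional to the per-item maxima, capped at those maxima.
allocate_score <- function(total, maxima) {
  k <- length(maxima)
  if (total <= 0) return(integer(k))
  total <- min(total, sum(maxima))
  share <- total * maxima / sum(maxima)
  base <- pmin(floor(share), maxima)
  rem <- total - sum(base)
  frac <- share - floor(share)
  ord <- order(frac, decreasing = TRUE)
  while (rem > 0) {
    before <- rem
    for (j in ord) {
      if (rem == 0) break
      if (base[j] < maxima[j]) {
        base[j] <- base[j] + 1
        rem <- rem - 1
      }
    }
    if (rem == before) break  # all at cap (cannot happen when total <= sum)
  }
  as.integer(base)
}

#' Generate a synthetic multisite cohort with planted ground truth
#'
#' Dimension-change signal is planted on the dimension-score scale -- a
#' site-level response profile, covariate slopes (age, sex, BMI, and the
#' dimension's own pretreatment severity), and sparse regional volume-change
#' slopes -- plus correlated residual noise; post-treatment items are then
#' derived by distributing each post dimension score back over its items by
#' proportional (largest-remainder) rounding and clipping to legal item
#' ranges. Additive and multiplicative site batch effects are applied to
#' the volume features *after* outcome assignment, so cross-site signal
#' recovery genuinely requires harmonization.
#'
#' @param config a [cohort_config()].
#' @return list with `subjects` (data.frame, one row per subject: id, site,
#'   covariates, psychotic flag, `hdrs_pre_01..17`, `hdrs_post_01..17`,
#'   `vol_change_<region>`) and `truth` (class `synthetic_truth`: planted
#'   region ids/betas per dimension, covariate betas, site shift/scale
#'   matrices, realized planted R-squared per dimension, and the noiseless
#'   signal matrix used by the recovery oracles).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  if (!is.null(config$seed))
    return(withr::with_seed(as.integer(config$seed),
                            generate_cohort_impl(config)))
  generate_cohort_impl(config)
}

generate_cohort_impl <- function(config) {
  n_i <- config$n_per_site
  n <- sum(n_i)
  S <- length(n_i)
  p <- config$n_regions
  dims <- c("sod", "cma", "insomnia")
  dim_max <- dimension_maxima()[dims]
  site <- factor(rep(config$site_names, n_i), levels = config$site_names)
  si <- as.integer(site)

  # --- covariates, site-dependent ------------------------------------
  age <- pmin(pmax(stats::rnorm(n, config$site_age_mean[si],
                                config$site_age_sd[si]), 18), 90)
  sex <- ifelse(stats::runif(n) < config$female_prob[si], "F", "M")
  bmi <- pmin(pmax(stats::rnorm(n, config$site_bmi_mean[si], config$bmi_sd),
                   15), 45)
  primary_tab <- matrix(c(25, 1, 1,
                          37, 2, 0,
                          1, 15, 0,
                          28, 0, 0), 4, 3, byrow = TRUE,
                        dimnames = list(NULL, c("RUL", "BT", "LART")))
  secondary_tab <- matrix(c(15, 11, 0, 1,
                            34, 5, 0, 0,
                            14, 0, 2, 0,
                            25, 3, 0, 0), 4, 4, byrow = TRUE,
                          dimnames = list(NULL, c("none", "BT", "RUL", "BF")))
  prim_idx <- rep_len(1:4, S)
  electrode_primary <- vapply(seq_len(n), function(i) {
    w <- primary_tab[prim_idx[si[i]], ]
    sample(colnames(primary_tab), 1L, prob = w / sum(w))
  }, character(1))
  electrode_secondary <- vapply(seq_len(n), function(i) {
    w <- secondary_tab[prim_idx[si[i]], ]
    sample(colnames(secondary_tab), 1L, prob = w / sum(w))
  }, character(1))
  # deterministic per-site psychotic counts (round(prob * n)) so fixtures
  # have a reproducible census; which subjects are flagged is random
  psychotic <- logical(n)
  for (s in seq_len(S)) {
    k <- round(config$psychotic_prob[s] * n_i[s])
    if (k > 0) {
      rows <- which(si == s)
      psychotic[sample(rows, k)] <- TRUE
    }
  }

  # --- baseline dimension scores --------------------------------------
  share_baseline <- config$baseline_mu / sum(config$baseline_mu)
  u <- stats::rnorm(n)  # shared severity factor
  e_b <- matrix(stats::rnorm(n * 3), n, 3)
  baseline <- matrix(0L, n, 3, dimnames = list(NULL, dims))
  for (k in 1:3) {
    mu_k <- config$baseline_mu[k] +
      config$site_baseline_shift[si] * share_baseline[k] * 3
    raw <- mu_k + config$baseline_sd[k] * (0.6 * u + 0.8 * e_b[, k])
    baseline[, k] <- pmin(pmax(round(raw), 0L), dim_max[k])
  }
  suicide_pre <- sample(0:4, n, replace = TRUE,
                        prob = c(0.25, 0.3, 0.25, 0.12, 0.08))
  insight_pre <- sample(0:2, n, replace = TRUE, prob = c(0.75, 0.17, 0.08))

  # --- true (pre-batch-effect) regional volume changes ----------------
  true_vol <- matrix(stats::rnorm(n * p), n, p)
  if (isTRUE(config$shared_informative_regions)) {
    shared_set <- if (config$n_informative_regions > 0)
      sort(sample.int(p, config$n_informative_regions)) else integer(0)
    shared_sign <- sample(c(-1, 1), config$n_informative_regions,
                          replace = TRUE)
    informative <- list(shared_set, shared_set, shared_set)
    beta_sign <- list(shared_sign, shared_sign, shared_sign)
  } else {
    informative <- lapply(1:3, function(k)
      if (config$n_informative_regions > 0)
        sort(sample.int(p, config$n_informative_regions)) else integer(0))
    beta_sign <- lapply(1:3, function(k)
      sample(c(-1, 1), config$n_informative_regions, replace = TRUE))
  }
  names(informative) <- dims

  # --- planted signal on the dimension-change scale -------------------
  # slopes are stated on the SoD scale and shrunk proportionally for the
  # narrower dimensions
  dim_scale <- config$baseline_sd / config$baseline_sd[1]
  ces <- config$covariate_effect_sizes
  null_world <- is.null(config$noise_sd) && config$planted_r2 == 0
  age_z <- (age - 50) / 15
  bmi_z <- (bmi - 26) / 5
  sex_c <- (sex == "F") - 0.5
  share_change <- if (sum(abs(config$mean_change)) == 0) rep(1 / 3, 3) else
    abs(config$mean_change) / sum(abs(config$mean_change))
  signal <- matrix(0, n, 3, dimnames = list(NULL, dims))
  region_betas <- informative
  covariate_betas <- matrix(0, 3, 4,
                            dimnames = list(dims, c("age", "sex", "bmi",
                                                    "baseline_severity")))
  for (k in 1:3) {
    bl_z <- (baseline[, k] - config$baseline_mu[k]) / config$baseline_sd[k]
    if (null_world) {
      region_betas[[k]] <- rep(0, config$n_informative_regions)
      next
    }
    covariate_betas[k, ] <- ces[c("age", "sex", "bmi", "baseline_severity")] *
      dim_scale[k]
    region_betas[[k]] <- beta_sign[[k]] * config$region_effect_size *
      dim_scale[k]
    signal[, k] <- config$site_change_shift[si] * share_change[k] +
      covariate_betas[k, "age"] * age_z +
      covariate_betas[k, "sex"] * sex_c +
      covariate_betas[k, "bmi"] * bmi_z +
      covariate_betas[k, "baseline_severity"] * bl_z
    if (config$n_informative_regions > 0)
      signal[, k] <- signal[, k] +
        true_vol[, informative[[k]], drop = FALSE] %*% region_betas[[k]]
  }

  # --- residual noise, calibrated to planted_r2 unless noise_sd given --
  eps_raw <- matrix(stats::rnorm(n * 3), n, 3)
  ev <- eigen(config$dim_change_corr, symmetric = TRUE)
  eps_raw <- eps_raw %*% (ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*%
                            t(ev$vectors))
  if (!is.null(config$noise_sd)) {
    nsd <- rep_len(config$noise_sd, 3)
  } else if (config$planted_r2 > 0) {
    r2 <- config$planted_r2
    nsd <- apply(signal, 2, stats::sd) * sqrt((1 - r2) / r2)
  } else {
    nsd <- 2.5 * dim_scale
  }
  names(nsd) <- dims
  eps <- sweep(eps_raw, 2, nsd, `*`)
  delta <- sweep(signal, 2, config$mean_change, `+`) + eps
  post <- matrix(0L, n, 3, dimnames = list(NULL, dims))
  for (k in 1:3)
    post[, k] <- pmin(pmax(round(baseline[, k] + delta[, k]), 0L), dim_max[k])
  suicide_post <- stats::rbinom(n, suicide_pre, 0.3)
  insight_post <- stats::rbinom(n, insight_pre, 0.3)

  # --- items via proportional rounding --------------------------------
  item_max <- stats::setNames(hdrs_items$max, hdrs_items$name)
  fill_items <- function(dim_scores, suicide, insight) {
    items <- matrix(0L, n, 17, dimnames = list(NULL, hdrs_items$name))
    for (i in seq_len(n)) {
      for (k in 1:3) {
        set <- hdrs_dimensions[[dims[k]]]
        items[i, set] <- allocate_score(dim_scores[i, k], item_max[set])
      }
    }
    items[, "suicide"] <- suicide
    items[, "insight"] <- insight
    items
  }
  pre_items <- fill_items(baseline, suicide_pre, insight_pre)
  post_items <- fill_items(post, suicide_post, insight_post)

  # --- site batch effects applied AFTER outcome assignment ------------
  site_shifts <- matrix(stats::rnorm(S * p, 0, config$site_shift_sd), S, p,
                        dimnames = list(config$site_names, NULL))
  site_scales <- matrix(stats::runif(S * p, config$site_scale_range[1],
                                     config$site_scale_range[2]), S, p,
                        dimnames = list(config$site_names, NULL))
  obs_vol <- true_vol * site_scales[si, , drop = FALSE] +
    site_shifts[si, , drop = FALSE]
  rn <- region_names(p)
  colnames(obs_vol) <- paste0("vol_change_", rn)
  colnames(site_shifts) <- colnames(site_scales) <- rn

  subjects <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    site = as.character(site),
    age = age, sex = sex, bmi = bmi,
    electrode_primary = electrode_primary,
    electrode_secondary = electrode_secondary,
    psychotic = psychotic,
    stringsAsFactors = FALSE)
  pre_df <- as.data.frame(pre_items)
  names(pre_df) <- sprintf("hdrs_pre_%02d", 1:17)
  post_df <- as.data.frame(post_items)
  names(post_df) <- sprintf("hdrs_post_%02d", 1:17)
  subjects <- cbind(subjects, pre_df, post_df, as.data.frame(obs_vol))
  rownames(subjects) <- NULL

  signal_total <- sweep(signal, 2, config$mean_change, `+`)
  planted_r2 <- vapply(1:3, function(k) {
    vs <- stats::var(signal[, k])
    if (vs == 0) 0 else vs / (vs + nsd[k]^2)
  }, numeric(1))
  names(planted_r2) <- dims
  truth <- structure(
    list(informative_region_ids = informative,
         region_betas = region_betas,
         covariate_betas = covariate_betas,
         site_shifts = site_shifts,
         site_scales = site_scales,
         planted_r2 = planted_r2,
         noise_sd = nsd,
         signal = signal_total,
         delta_target = delta,
         true_volumes = true_vol,
         region_names = rn,
         config = config),
    class = "synthetic_truth")
  list(subjects = subjects, truth = truth)
}

#' Pearson correlations of the three dimension-change scores
#'
#' @param cohort cohort data.frame with complete pre/post HDRS item columns.
#' @return symmetric 3x3 correlation matrix (`sod`, `cma`, `insomnia`).
#' @export
dimension_change_correlations <- function(cohort) {
  scored <- score_cohort(cohort)
  ch <- as.matrix(scored$change[, c("sod", "cma", "insomnia")])
  ch <- ch[stats::complete.cases(ch), , drop = FALSE]
  if (nrow(ch) < 3L)
    stop("dimension_change_correlations: fewer than 3 complete subjects")
  stats::cor(ch)
}
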
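test_that("residualize_fit matches the normal-equations oracle", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  y <- matrix(c(1, 3, 5, 7), ncol = 1, dimnames = list(NULL, "f"))
  rp <- residualize_fit(y, x)
  expect_equal(unname(rp$betas[, 1]), c(1, 2))
  expect_equal(max(abs(residualize_apply(rp, y, x))), 0)
  # apply params from y = 1 + 2x to new points
  expect_equal(as.numeric(residualize_apply(
    rp, matrix(21), matrix(10, dimnames = list(NULL, "x")))), 0)
  expect_equal(as.numeric(residualize_apply(
    rp, matrix(5), matrix(0, dimnames = list(NULL, "x")))), 4)
})

test_that("residualization degenerate cases behave per contract", {
  set.seed(1)
  cov <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  # feature identical to a covariate -> zero residuals
  rp <- residualize_fit(matrix(cov[, 1], ncol = 1), cov)
  expect_lt(max(abs(residualize_apply(rp, matrix(cov[, 1], ncol = 1), cov))),
            1e-10)
  # covariate of zeros (plus intercept): residual = feature - mean
  z <- matrix(0, 20, 1, dimnames = list(NULL, "z"))
  f <- matrix(stats::rnorm(20), ncol = 1)
  rz <- residualize_fit(f, z)
  expect_equal(as.numeric(residualize_apply(rz, f, z)),
               as.numeric(f - mean(f)))
  # rank-deficiency error names the collinear column
  cov2 <- cbind(cov, dup = cov[, 1])
  expect_error(residualize_fit(f, cov2), "dup")
})

test_that("training residuals are orthogonal to every covariate", {
  set.seed(2)
  cov <- matrix(stats::rnorm(150), 50, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  feats <- matrix(stats::rnorm(50 * 8), 50, 8)
  rp <- residualize_fit(feats, cov)
  res <- residualize_apply(rp, feats, cov)
  for (j in 1:3)
    expect_lt(max(abs(stats::cor(res, cov[, j]))), 1e-8)
  # fit/apply separation: deleting rows never changes fitted parameters
  rp2 <- residualize_fit(feats[1:30, ], cov[1:30, ])
  expect_identical(rp2$betas,
                   residualize_fit(feats[1:30, ], cov[1:30, ])$betas)
  expect_equal(residualize_apply(rp, feats, cov)[1:10, ],
               residualize_apply(rp, feats[1:10, ], cov[1:10, ]))
})

test_that("harmonization recovers a pure additive offset exactly", {
  set.seed(5)
  base <- matrix(stats::rnorm(240), 40, 6,
                 dimnames = list(NULL, paste0("f", 1:6)))
  x <- rbind(base, base + 5)
  site <- rep(c("a", "b"), each = 40)
  hp <- harmonize_fit(x, site, method = "direct")
  locs <- site_location_estimates(hp)
  expect_lt(max(abs((locs["b", ] - locs["a", ]) - 5)), 1e-6)
  adj <- hp$adjusted
  expect_lt(max(abs(colMeans(adj[site == "a", ]) -
                      colMeans(adj[site == "b", ]))), 1e-8)
  # grand mean preserved per feature
  expect_lt(max(abs(colMeans(adj) - colMeans(x))), 1e-6)
  # apply-to-train equals in-sample adjusted
  expect_equal(harmonize_apply(hp, x, site), adj)
  # plug-in arithmetic: a params object whose stored location effect for
  # site b is +5 (on the raw scale) and scale 1 subtracts exactly 5
  hp5 <- hp
  hp5$gamma_star <- rbind(a = rep(0, 6), b = 5 / sqrt(hp$var_pooled))
  hp5$delta_star <- matrix(1, 2, 6, dimnames = dimnames(hp5$gamma_star))
  newx <- matrix(stats::rnorm(6) + 5, 1, 6,
                 dimnames = list(NULL, paste0("f", 1:6)))
  expect_equal(harmonize_apply(hp5, newx, "b"), newx - 5,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(harmonize_apply(hp5, newx, "a"), newx,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("single-site harmonization is a no-op; contracts enforced", {
  set.seed(6)
  x <- matrix(stats::rnorm(200), 20, 10)
  expect_lt(max(abs(harmonize_fit(x, rep("s", 20),
                                  method = "direct")$adjusted - x)), 1e-8)
  expect_error(harmonize_fit(x, c("a", rep("b", 19))), "< 2 subjects")
  hp <- harmonize_fit(x, rep(c("a", "b"), 10))
  expect_error(harmonize_apply(hp, x, rep("c", 20)), "pseudo")
  # params from no-batch-effect data: apply is ~identity (deviations are
  # location/scale sampling noise, O(1/sqrt(n)) per feature SD)
  big <- matrix(stats::rnorm(400 * 10), 400, 10)
  hp2 <- harmonize_fit(big, rep(c("a", "b"), 200), method = "direct")
  expect_lt(mean(abs(hp2$adjusted - big)), 0.05)
  expect_lt(max(abs(colMeans(hp2$adjusted) - colMeans(big))), 0.05)
})

test_that("empirical-Bayes estimates shrink toward the prior mean", {
  gen <- generate_cohort(cohort_config(n_per_site = rep(30L, 4),
                                       n_regions = 30L, site_shift_sd = 0.5,
                                       seed = 13))
  x <- imaging_matrix(gen$subjects)
  hp <- harmonize_fit(x, gen$subjects$site, method = "empirical_bayes")
  for (i in seq_along(hp$sites)) {
    g_bar <- mean(hp$gamma_hat[i, ])
    lo <- pmin(hp$gamma_hat[i, ], g_bar) - 1e-10
    hi <- pmax(hp$gamma_hat[i, ], g_bar) + 1e-10
    expect_true(all(hp$gamma_star[i, ] >= lo & hp$gamma_star[i, ] <= hi))
    # scale estimates move toward (not past) the bulk of the prior
    moved_in <- abs(hp$delta_star[i, ] - mean(hp$delta_hat[i, ])) <=
      abs(hp$delta_hat[i, ] - mean(hp$delta_hat[i, ])) + 0.05
    expect_gt(mean(moved_in), 0.9)
  }
})

test_that("harmonization reduces planted between-site F statistics", {
  gen <- generate_cohort(cohort_config(n_per_site = rep(40L, 4),
                                       n_regions = 40L, site_shift_sd = 0.6,
                                       seed = 8))
  x <- imaging_matrix(gen$subjects)
  s <- gen$subjects$site
  hp <- harmonize_fit(x, s)
  f0 <- site_f_stats(x, s)
  f1 <- site_f_stats(hp$adjusted, s)
  expect_gt(mean(f1 < f0), 0.9)
})

test_that("pseudo-site labels recover separable sites", {
  set.seed(9)
  p <- 15
  mk <- function(n, shift) matrix(stats::rnorm(n * p), n, p) +
    matrix(shift, n, p, byrow = TRUE)
  shift_a <- stats::rnorm(p, 0, 2)
  shift_b <- stats::rnorm(p, 0, 2)
  train <- rbind(mk(100, shift_a), mk(100, shift_b))
  labels <- rep(c("A", "B"), each = 100)
  heldout_a <- mk(100, shift_a)  # same distribution as site A
  pl <- pseudo_site_labels(train, labels, heldout_a, num_trees = 300,
                           seed = 2)
  expect_gte(mean(pl == "A"), 0.8)
  # equidistant held-out data from two identical-distribution sites
  train2 <- mk(200, rep(0, p))
  labels2 <- rep(c("A", "B"), 100)
  pl2 <- pseudo_site_labels(train2, labels2, mk(200, rep(0, p)),
                            num_trees = 300, seed = 3)
  expect_lt(abs(mean(pl2 == "A") - 0.5), 0.15)
  # single training site: constant labels with a warning
  expect_warning(
    pl3 <- pseudo_site_labels(train[1:50, ], rep("A", 50), heldout_a),
    "single")
  expect_true(all(pl3 == "A"))
})

test_that("encoders freeze imputation and level encodings", {
  df <- data.frame(age = c(50, NA, 60, 70), sex = c("F", "M", NA, "F"),
                   stringsAsFactors = FALSE)
  enc <- encoder_fit(df)
  m <- encoder_apply(enc, df)
  expect_equal(m[2, "age"], 60)       # training median
  expect_equal(unname(m[3, "sex_M"]), 0)  # mode-imputed to reference F
  expect_error(encoder_apply(enc, data.frame(age = 1, sex = "X")),
               "unseen")
  m2 <- encoder_apply(enc, data.frame(age = 1, sex = "X"),
                      strict_levels = FALSE)
  expect_equal(unname(m2[1, "sex_M"]), 0)
})

test_that("fitted transforms survive a JSON round trip", {
  set.seed(10)
  cov <- matrix(stats::rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  feats <- matrix(stats::rnorm(90), 30, 3,
                  dimnames = list(NULL, paste0("f", 1:3)))
  rp <- residualize_fit(feats, cov)
  tf <- withr::local_tempfile(fileext = ".json")
  write_transform(rp, tf)
  rp2 <- read_transform(tf)
  expect_equal(residualize_apply(rp2, feats, cov),
               residualize_apply(rp, feats, cov))
  hp <- harmonize_fit(feats, rep(c("a", "b"), 15))
  tf2 <- withr::local_tempfile(fileext = ".json")
  write_transform(hp, tf2)
  hp2 <- read_transform(tf2)
  expect_equal(harmonize_apply(hp2, feats, rep(c("a", "b"), 15)),
               hp$adjusted, tolerance = 1e-12)
})
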
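# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# default 110-subject, 4-site cohort
default_cohort <- function() {
  cached("default", generate_cohort(cohort_config(seed = 42)))
}

# small balanced cohort for cheap pipeline runs
small_cohort <- function() {
  cached("small", generate_cohort(
    cohort_config(n_per_site = rep(20L, 4), n_regions = 20L, seed = 7)))
}

# no planted signal anywhere (outcome is pure noise)
null_config <- function(n_per_site = rep(15L, 4), n_regions = 20L,
                        seed = 1L) {
  cohort_config(n_per_site = n_per_site, n_regions = n_regions,
                planted_r2 = 0, site_change_shift = rep(0, 4), seed = seed)
}

imaging_matrix <- function(cohort) {
  as.matrix(cohort[, grep("^vol_change_", names(cohort)), drop = FALSE])
}

# between-site one-way ANOVA F statistic for every feature column
site_f_stats <- function(x, site) {
  site <- factor(site)
  apply(x, 2, function(v) stats::anova(stats::lm(v ~ site))$`F value`[1])
}
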
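# Shared desk-scale fixtures. Everything is generated in code at test time;
# sizes are chosen so whole-pipeline tests run in seconds.

tiny_generator <- function(...) {
  args <- list(...)
  defaults <- list(
    n_train = 60, n_test = 40, n_bd = 40, n_mdd = 24,
    grid_dim = c(12, 12, 12), n_regions_gm = 3, n_regions_wm = 2,
    voxels_per_region = 20, seed = 42
  )
  do.call(generator_config, utils::modifyList(defaults, args))
}

tiny_selection <- function(...) {
  args <- list(...)
  defaults <- list(n_inner = 20, n_outer = 2, seed = 42)
  do.call(selection_config, utils::modifyList(defaults, args))
}

# Columns with an exact target correlation to `ages`: r * u_age plus an
# orthogonal unit-norm residual direction.
matrix_with_correlations <- function(ages, r_target, seed = 1) {
  n <- length(ages)
  u <- ages - mean(ages)
  u <- u / sqrt(sum(u^2))
  withr::with_seed(seed, {
    sapply(r_target, function(r) {
      z <- rnorm(n)
      z <- z - mean(z)
      z <- z - u * sum(u * z)
      z <- z / sqrt(sum(z^2))
      r * u + sqrt(1 - r^2) * z
    })
  })
}

# 4-row toy phenotype table used by the I/O tests.
toy_cohort_df <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3", "s4"),
    age = c(25, 40, 63, 80),
    sex = c("male", "female", "female", "male"),
    group = c("HC_train", "HC_test", "BD", "MDD"),
    mmse = c(29, 30, 27, NA),
    education = c(16, 12, 14, 9),
    ymrs = c(NA, NA, 12, NA),
    hamd21 = c(NA, NA, 8, 19),
    hama = c(NA, NA, 7, 15),
    illness_duration = c(NA, NA, 6.5, 2.1)
  )
}
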
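test_that("voxel-age correlations match a brute-force Pearson computation", {
  ages <- c(23, 31, 47, 60, 78)
  x <- withr::with_seed(2, matrix(rnorm(5 * 4), 5, 4))
  x[, 1] <- ages                 # perfect correlation
  x[, 2] <- -2 * ages + 7        # perfect anticorrelation
  x[, 4] <- 3                    # zero variance
  r <- voxel_age_correlation(x, ages)
  expect_equal(r[1], 1)
  expect_equal(r[2], -1)
  expect_true(is.na(r[4]))
  # explicit covariance / variance oracle for the generic column
  brute <- sum((x[, 3] - mean(x[, 3])) * (ages - mean(ages))) /
    sqrt(sum((x[, 3] - mean(x[, 3]))^2) * sum((ages - mean(ages))^2))
  expect_equal(r[3], brute, tolerance = 1e-12)
  expect_equal(r[3], cor(x[, 3], ages), tolerance = 1e-12)
})

test_that("degenerate correlation inputs raise errors", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(voxel_age_correlation(x, rep(50, 4)),
    class = "regionbag_degenerate_error")
  expect_error(voxel_age_correlation(x[1:2, ], c(30, 40)),
    class = "regionbag_degenerate_error")
})

test_that("iteration sets keep the top fraction by |r| with a deterministic tie rule", {
  ages <- seq(25, 75, length.out = 40)
  cfg <- selection_config(subsample_fraction = 1, top_fraction = 0.5,
    n_inner = 1, n_outer = 1)
  x <- matrix_with_correlations(ages, c(0.9, -0.5, 0.4, 0.1), seed = 3)
  set1 <- select_iteration_set(x, ages, cfg, iter_seed = 1)
  expect_equal(set1, c(1L, 2L))  # |r| = 0.9 and 0.5 win; sign is ignored
  # exact tie at the cutoff: duplicated column, lower index wins
  xt <- cbind(x[, 1], x[, 3], x[, 3], x[, 4])
  sett <- select_iteration_set(xt, ages, cfg, iter_seed = 1)
  expect_equal(sett, c(1L, 2L))
  # signed mode ranks by r itself, discarding strong negatives
  cfg_s <- selection_config(subsample_fraction = 1, top_fraction = 0.5,
    n_inner = 1, n_outer = 1, signed = TRUE)
  expect_equal(select_iteration_set(x, ages, cfg_s, iter_seed = 1), c(1L, 3L))
})

test_that("seeded iterations are reproducible and subsample without replacement", {
  ages <- runif(30, 20, 84)
  x <- matrix_with_correlations(ages, runif(10, -0.8, 0.8), seed = 4)
  cfg <- selection_config(subsample_fraction = 0.7, top_fraction = 0.5)
  s1 <- select_iteration_set(x, ages, cfg, iter_seed = 99)
  s2 <- select_iteration_set(x, ages, cfg, iter_seed = 99)
  expect_identical(s1, s2)
  # across many iteration seeds the subsample, and hence the set, must vary
  others <- lapply(100:119, function(sd) select_iteration_set(x, ages, cfg, sd))
  expect_gt(length(unique(others)), 1)
})

test_that("consensus over iterations matches counting oracles", {
  cfg <- selection_config()
  # idempotence on identical sets
  expect_equal(intersect_iterations(rep(list(c(2L, 5L, 9L)), 7), cfg),
    c(2L, 5L, 9L))
  # strict intersection enumeration
  sets <- list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L, 5L))
  expect_equal(intersect_iterations(sets, cfg), 3L)
  # quantile consensus equals a brute-force frequency count
  rand_sets <- withr::with_seed(8,
    lapply(1:10, function(i) sort(sample.int(20, 8))))
  cfg8 <- selection_config(consensus_quantile = 0.8)
  counts <- table(unlist(rand_sets))
  oracle <- sort(as.integer(names(counts)[counts >= ceiling(0.8 * 10)]))
  expect_equal(intersect_iterations(rand_sets, cfg8), oracle)
})

test_that("an empty strict intersection falls back to 0.9 consensus with a warning", {
  sets <- c(rep(list(c(1L, 2L)), 19), list(c(3L, 4L)))
  expect_warning(out <- intersect_iterations(sets, selection_config()),
    class = "regionbag_consensus_fallback")
  expect_equal(as.integer(out), c(1L, 2L))
  expect_true(isTRUE(attr(out, "fallback")))
})

test_that("raising the consensus quantile never grows the consensus set", {
  rand_sets <- withr::with_seed(13,
    lapply(1:12, function(i) sort(sample.int(15, 6))))
  sizes <- sapply(c(0.5, 0.7, 0.9, 1.0), function(q) {
    length(suppressWarnings(intersect_iterations(rand_sets,
      selection_config(consensus_quantile = q))))
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("key-voxel sets are the union of outer consensus sets with frequencies", {
  ages <- runif(40, 20, 84)
  x <- matrix_with_correlations(ages, runif(12, -0.9, 0.9), seed = 6)
  cfg1 <- tiny_selection(n_outer = 1)
  keys1 <- build_key_voxel_sets(x, ages, cfg1)
  # n_outer = 1 reduces to a single consensus set
  inner <- lapply(seq_len(cfg1$n_inner), function(i)
    select_iteration_set(x, ages, cfg1, regionbag:::mix_seed(cfg1$seed, 0, 0, 1, i)))
  expect_equal(keys1$cols,
    as.integer(suppressWarnings(intersect_iterations(inner, cfg1))))
  # frequencies count outer-set membership
  cfg3 <- tiny_selection(n_outer = 3)
  keys3 <- build_key_voxel_sets(x, ages, cfg3)
  expect_true(all(keys3$frequency >= 1 & keys3$frequency <= 3))
  expect_true(all(keys1$cols %in% keys3$cols))
})

test_that("selection is invariant to voxel column permutation up to relabelling", {
  ages <- runif(36, 20, 84)
  x <- matrix_with_correlations(ages, runif(10, -0.9, 0.9), seed = 7)
  cfg <- tiny_selection()
  keys <- build_key_voxel_sets(x, ages, cfg)
  perm <- withr::with_seed(10, sample(ncol(x)))
  keys_p <- build_key_voxel_sets(x[, perm], ages, cfg)
  expect_equal(sort(perm[keys_p$cols]), keys$cols)
})

test_that("in the noiseless limit exactly the informative voxels are selected", {
  cfg <- tiny_generator(noise_sd = 0, informative_fraction = 0.5)
  study <- generate_study(cfg)
  train <- which(study$cohort$group == "HC_train")
  regs <- parcellate(study$maps$GM, study$atlases$gray_matter, study$cohort)
  rg <- regs[["G01.L"]]
  rg$x <- rg$x[train, , drop = FALSE]
  keys <- build_key_voxel_sets(rg, study$cohort$age[train],
    tiny_selection(top_fraction = 0.5))
  tru <- study$truth[study$truth$modality == "GM" &
    study$truth$region == "G01.L", ]
  expect_setequal(keys$voxels, tru$voxel_index[tru$informative])
})

test_that("strict 1000-fold intersection eliminates almost all pure-noise voxels", {
  # Iterations subsample one fixed cohort, so per-voxel rank positions are
  # dependent across iterations: a noise voxel whose whole-sample |r| sits
  # far above the rank cutoff by chance can persist every draw. Strict
  # intersection therefore removes almost all, but not provably all, of the
  # 50% of noise voxels a single iteration retains.
  cfg <- selection_config(n_inner = 1000, n_outer = 1)
  strict <- sapply(1:5, function(trial) {
    ages <- withr::with_seed(trial, runif(60, 20, 84))
    x <- withr::with_seed(1000 + trial, matrix(rnorm(60 * 40), 60, 40))
    counts <- table(unlist(lapply(seq_len(1000), function(i)
      select_iteration_set(x, ages, cfg,
        regionbag:::mix_seed(trial, 0, 0, 1, i)))))
    sum(counts == 1000)
  })
  expect_true(all(strict <= 2))
  expect_gte(sum(strict == 0), 3)
})
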
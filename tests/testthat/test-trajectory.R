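# Shared noiseless study: every voxel an exact affine function of age.
noiseless_study <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- generate_study(tiny_generator(noise_sd = 0, pure_noise_sd = 0,
        informative_fraction = 1))
    }
    value
  }
})

test_that("the noiseless fixture is learned almost perfectly", {
  study <- noiseless_study()
  train <- which(study$cohort$group == "HC_train")
  regs <- parcellate(study$maps$GM, study$atlases$gray_matter, study$cohort)
  rg <- regionbag:::region_subset(regs[["G01.L"]], train)
  model <- fit_region_model(rg, study$cohort$age[train], seed = 1)
  cv <- model$cv_prediction
  expect_lt(mean(abs(cv$raw - cv$age)), 0.5)
  expect_gt(cor(cv$raw, cv$age), 0.99)
})

test_that("a mean-profile subject is predicted at its generating age", {
  study <- noiseless_study()
  cohort <- study$cohort
  train <- which(cohort$group == "HC_train")
  regs <- parcellate(study$maps$GM, study$atlases$gray_matter, cohort)
  rg <- regionbag:::region_subset(regs[["G01.L"]], train)
  model <- fit_region_model(rg, cohort$age[train], seed = 1)
  tru <- study$truth[study$truth$modality == "GM" &
    study$truth$region == "G01.L", ]
  probe <- matrix(tru$b0 + tru$b1 * 40, nrow = 1)
  pred <- predict(model$gpr,
    regionbag:::apply_standardize(probe[, model$key_cols, drop = FALSE],
      model$standardize))
  expect_equal(pred, 40, tolerance = 0.5)
})

test_that("fold assignment is seeded, stratified, and reproducible", {
  ages <- withr::with_seed(20, runif(50, 20, 84))
  f1 <- regionbag:::cv_folds_stratified(ages, 5, seed = 3)
  f2 <- regionbag:::cv_folds_stratified(ages, 5, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  # each age quintile is spread across folds
  q <- dplyr::ntile(ages, 5)
  tab <- table(q, f1)
  expect_true(all(tab <= 3))
  expect_false(identical(f1, regionbag:::cv_folds_stratified(ages, 5, seed = 4)))
})

test_that("shuffled-age training yields no age signal", {
  study <- noiseless_study()
  cohort <- study$cohort
  train <- which(cohort$group == "HC_train")
  regs <- parcellate(study$maps$GM, study$atlases$gray_matter, cohort)
  rg <- regionbag:::region_subset(regs[["G01.L"]], train)
  rs <- sapply(1:10, function(s) {
    ages_perm <- withr::with_seed(100 + s, sample(cohort$age[train]))
    m <- fit_region_model(rg, ages_perm, seed = s)
    cor(m$cv_prediction$raw, ages_perm)
  })
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("bias-correction coefficients match the OLS closed form", {
  # forced coefficients
  ages <- seq(20, 84, length.out = 33)
  bc_id <- fit_bias_correction(ages, ages)
  expect_equal(bc_id$alpha, 1, tolerance = 1e-12)
  expect_equal(bc_id$beta, 0, tolerance = 1e-10)
  bc <- fit_bias_correction(0.5 * ages + 20, ages)
  expect_equal(bc$alpha, 0.5, tolerance = 1e-12)
  expect_equal(bc$beta, 20, tolerance = 1e-10)
  # noisy case against a hand-rolled normal-equations oracle
  raw <- withr::with_seed(21, 0.8 * ages + 5 + rnorm(33, sd = 3))
  bcn <- fit_bias_correction(raw, ages)
  xm <- cbind(1, ages)
  oracle <- solve(t(xm) %*% xm, t(xm) %*% raw)
  expect_equal(bcn$beta, oracle[1], tolerance = 1e-10)
  expect_equal(bcn$alpha, oracle[2], tolerance = 1e-10)
})

test_that("degenerate bias corrections are refused", {
  ages <- seq(20, 84, length.out = 20)
  expect_error(fit_bias_correction(rep(40, 20), ages),
    class = "regionbag_correction_degenerate_error")
  expect_error(fit_bias_correction(c(30, 40), c(25, 35)),
    class = "regionbag_degenerate_error")
  expect_error(fit_bias_correction(rnorm(5) + 40, rep(50, 5)),
    class = "regionbag_degenerate_error")
})

test_that("the offset correction satisfies its algebraic identities", {
  ages <- withr::with_seed(22, runif(120, 20, 84))
  raw <- withr::with_seed(23, 0.6 * ages + 18 + rnorm(120, sd = 4))
  bc <- fit_bias_correction(raw, ages)
  out <- apply_bias_correction(raw, ages, bc)
  # BAG identity holds exactly
  expect_equal(out$bag, raw - (bc$alpha * ages + bc$beta), tolerance = 1e-12)
  expect_equal(out$bag, out$corrected - ages, tolerance = 1e-12)
  # on the fitting population, corrected vs age has slope 1, intercept 0
  refit <- lm(out$corrected ~ ages)
  expect_equal(unname(coef(refit)[2]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(refit)[1]), 0, tolerance = 1e-8)
  # and corr(BAG, age) vanishes by OLS orthogonality
  expect_lt(abs(cor(out$bag, ages)), 1e-8)
  # identity correction leaves raw untouched
  out_id <- apply_bias_correction(raw, ages,
    structure(list(alpha = 1, beta = 0), class = "bias_correction"))
  expect_equal(out_id$corrected, raw)
  # a perfectly linear raw signal is corrected to zero BAG
  out_lin <- apply_bias_correction(0.5 * ages + 20, ages,
    fit_bias_correction(0.5 * ages + 20, ages))
  expect_equal(out_lin$bag, rep(0, 120), tolerance = 1e-10)
})

test_that("the divisive correction inverts the linear bias", {
  ages <- seq(20, 84, length.out = 30)
  raw <- 0.5 * ages + 20
  bc <- fit_bias_correction(raw, ages)
  out <- apply_bias_correction(raw, ages, bc, form = "divisive")
  expect_equal(out$corrected, ages, tolerance = 1e-10)
})

test_that("performance metrics handle perfect and degenerate predictors", {
  ages <- seq(20, 84, length.out = 25)
  perfect <- tibble::tibble(population = "test", age = ages, raw = ages,
    corrected = ages)
  perf <- evaluate_performance(perfect)
  expect_equal(perf$mae_corrected, 0)
  expect_equal(perf$r_corrected, 1)
  constant <- tibble::tibble(population = "test", age = ages, raw = 40,
    corrected = 40)
  perf_c <- evaluate_performance(constant)
  expect_true(is.na(perf_c$r_raw))
  expect_equal(perf_c$mae_raw, mean(abs(40 - ages)))
})

test_that("tidy and glance expose model summaries", {
  study <- noiseless_study()
  train <- which(study$cohort$group == "HC_train")
  regs <- parcellate(study$maps$GM, study$atlases$gray_matter, study$cohort)
  rg <- regionbag:::region_subset(regs[["G01.L"]], train)
  model <- fit_region_model(rg, study$cohort$age[train], seed = 1)
  model$bias <- fit_bias_correction(model$cv_prediction$raw,
    study$cohort$age[train])
  td <- tidy(model)
  expect_setequal(td$term, c("bias_alpha", "bias_beta",
    "gpr_signal_variance", "gpr_noise_variance"))
  gl <- glance(model)
  expect_equal(gl$region, "G01.L")
  expect_lt(gl$mae_cv, 0.5)
})

test_that("removing non-training populations changes no fitted quantity", {
  cfg <- tiny_generator(seed = 33)
  study <- generate_study(cfg)
  cohort <- study$cohort
  train <- which(cohort$group == "HC_train")
  regs <- parcellate(study$maps$GM, study$atlases$gray_matter, cohort)
  rg_full <- regs[["G01.L"]]
  rg_tr <- regionbag:::region_subset(rg_full, train)
  keys <- build_key_voxel_sets(rg_tr, cohort$age[train], tiny_selection())
  m1 <- fit_region_model(rg_tr, cohort$age[train], keys, seed = 5)
  # corrupt every non-training row: fits must not notice
  rg_bad <- rg_full
  nontrain <- setdiff(seq_len(nrow(rg_bad$x)), train)
  rg_bad$x[nontrain, ] <- withr::with_seed(1,
    matrix(rnorm(length(nontrain) * ncol(rg_bad$x)), length(nontrain)))
  hc_only <- regionbag:::region_subset(rg_bad, train)
  keys2 <- build_key_voxel_sets(hc_only, cohort$age[train], tiny_selection())
  m2 <- fit_region_model(hc_only, cohort$age[train], keys2, seed = 5)
  expect_identical(keys2$cols, keys$cols)
  expect_equal(m2$gpr$alpha, m1$gpr$alpha, tolerance = 0)
  expect_equal(m2$cv_prediction$raw, m1$cv_prediction$raw, tolerance = 0)
})
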
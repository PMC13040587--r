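test_that("matched-control sampling hits the target size and sex ratio", {
  cohort <- generate_cohort(generator_config(seed = 4))
  mc <- sample_matched_controls(cohort, "MDD", seed = 1)
  expect_equal(mc$n, 68)
  picked <- cohort[cohort$subject_id %in% mc$control_ids, ]
  expect_equal(nrow(picked), 68)
  expect_true(all(picked$group == "HC_test"))
  expect_equal(sum(picked$sex == "female"),
    round(mean(cohort$sex[cohort$group == "MDD"] == "female") * 68))
  expect_false(any(duplicated(mc$control_ids)))
  # seeded repeat is identical; a different seed differs
  expect_identical(sample_matched_controls(cohort, "MDD", seed = 1)$control_ids,
    mc$control_ids)
  expect_false(identical(
    sample_matched_controls(cohort, "MDD", seed = 2)$control_ids,
    mc$control_ids))
})

test_that("a target as large as the pool selects the whole pool", {
  cohort <- generate_cohort(tiny_generator(n_test = 30, n_bd = 30,
    sex_ratio = list(HC_train = 0.5, HC_test = 0.5, BD = 0.5, MDD = 0.5)))
  mc <- sample_matched_controls(cohort, "BD", seed = 1)
  expect_setequal(mc$control_ids,
    cohort$subject_id[cohort$group == "HC_test"])
})

test_that("an insufficient control pool is a matching error with a shortfall report", {
  cohort <- generate_cohort(tiny_generator(n_test = 10, n_bd = 30))
  expect_error(sample_matched_controls(cohort, "BD", seed = 1),
    class = "regionbag_matching_error")
})

test_that("ANCOVA matches a brute-force residual-SS oracle exactly", {
  d <- tibble::tibble(
    bag = c(1.2, -0.5, 2.0, 0.3, 3.1, 2.4, -1.0, 1.8),
    group = rep(c("BD", "HC"), each = 4),
    age = c(30, 45, 60, 70, 35, 50, 62, 71),
    sex = c("male", "female", "male", "female",
      "male", "female", "male", "female"),
    mmse = c(29, 28, 30, 27, 29, 30, 26, 28),
    education = c(16, 12, 14, 10, 15, 13, 11, 17)
  )
  res <- ancova_bag(d)
  # oracle: explicit design matrices and residual sums of squares
  g <- as.numeric(d$group == "BD")
  sexn <- as.numeric(d$sex == "female")
  xf <- cbind(1, g, d$age, sexn, d$mmse, d$education)
  xr <- xf[, -2]
  rss <- function(xm) {
    beta <- solve(t(xm) %*% xm, t(xm) %*% d$bag)
    sum((d$bag - xm %*% beta)^2)
  }
  ss_f <- rss(xf); ss_r <- rss(xr)
  f_oracle <- (ss_r - ss_f) / (ss_f / (nrow(d) - ncol(xf)))
  eta_oracle <- (ss_r - ss_f) / ((ss_r - ss_f) + ss_f)
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_equal(res$partial_eta2, eta_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(f_oracle, 1, nrow(d) - ncol(xf), lower.tail = FALSE),
    tolerance = 1e-12)
  expect_equal(res$n, 8)
})

test_that("identical groups with constant covariates give a null ANCOVA", {
  d <- tibble::tibble(
    bag = rep(c(1, 2, 3, 4, 5), 2),
    group = rep(c("BD", "HC"), each = 5),
    age = rep(50, 10)
  )
  res <- ancova_bag(d, covariates = "age")
  expect_equal(res$f, 0, tolerance = 1e-12)
  expect_equal(res$partial_eta2, 0, tolerance = 1e-12)
  expect_equal(res$mean_bag_patient, res$mean_bag_control)
})

test_that("ANCOVA F is invariant to affine rescaling of covariates", {
  d <- withr::with_seed(30, tibble::tibble(
    bag = rnorm(40),
    group = rep(c("MDD", "HC"), each = 20),
    age = runif(40, 20, 84),
    mmse = round(runif(40, 24, 30))
  ))
  r1 <- ancova_bag(d, covariates = c("age", "mmse"))
  d2 <- dplyr::mutate(d, age = (age - 50) / 10, mmse = 3 * mmse + 7)
  r2 <- ancova_bag(d2, covariates = c("age", "mmse"))
  expect_equal(r1$f, r2$f, tolerance = 1e-9)
  expect_equal(r1$partial_eta2, r2$partial_eta2, tolerance = 1e-9)
})

test_that("collinear designs raise an estimation error and missing values are dropped", {
  d <- withr::with_seed(31, tibble::tibble(
    bag = rnorm(20),
    group = rep(c("BD", "HC"), each = 10),
    age = runif(20, 20, 80)
  ))
  d$age2 <- 2 * d$age
  expect_error(ancova_bag(d, covariates = c("age", "age2")),
    class = "regionbag_estimation_error")
  d3 <- d
  d3$age[1:3] <- NA
  res <- ancova_bag(d3, covariates = "age")
  expect_equal(res$n, 17)
})

test_that("BY adjustment equals step-up enumeration and dominates BH", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  # brute-force BY step-up
  ord <- order(p)
  stepup <- rev(cummin(rev(pmin(1, m * cm * p[ord] / seq_len(m)))))
  oracle <- numeric(m); oracle[ord] <- stepup
  expect_equal(fdr_adjust(p, "BY"), oracle, tolerance = 1e-12)
  # edge cases
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(rep(1, 6)), rep(1, 6))
  expect_error(fdr_adjust(c(0.1, 1.2)), class = "regionbag_validation_error")
  # BY is never less conservative than BH
  pv <- withr::with_seed(32, runif(50)^2)
  expect_true(all(fdr_adjust(pv, "BY") >= fdr_adjust(pv, "BH") - 1e-12))
})

test_that("acceleration flags require both significance and direction", {
  res <- tibble::tibble(
    region = c("a", "b", "c"),
    p_adj = c(0.01, 0.01, 0.2),
    mean_bag_patient = c(2, -1, 3),
    mean_bag_control = c(0, 1, 0)
  )
  out <- flag_accelerated(res)
  expect_equal(out$accelerated, c(TRUE, FALSE, FALSE))
})

test_that("partial correlation matches the recursion-formula oracle", {
  withr::with_seed(33, {
    z <- rnorm(6)
    x <- 0.5 * z + rnorm(6)
    y <- -0.3 * z + rnorm(6)
  })
  res <- partial_correlation(x, y, data.frame(z = z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$r, oracle, tolerance = 1e-10)
  expect_equal(res$df, 6 - 2 - 1)
  # no covariates reduces to plain Pearson
  plain <- partial_correlation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$p, cor.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("a variable built from BAG plus covariate noise has partial r near 1", {
  withr::with_seed(34, {
    age <- runif(60, 20, 84)
    bag <- rnorm(60)
    clin <- bag + 0.1 * age
  })
  res <- partial_correlation(bag, clin, data.frame(age = age))
  expect_gt(res$r, 0.999)
})

test_that("degenerate partial-correlation inputs raise errors", {
  expect_error(partial_correlation(1:4, 2:5), class = "regionbag_degenerate_error")
  z <- data.frame(z = 1:10)
  expect_error(partial_correlation(rep(1, 10), rnorm(10)),
    class = "regionbag_degenerate_error")
})
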
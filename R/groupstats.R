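#' Group comparison of brain-age gaps
#'
#' Patients are compared with sex-ratio-matched controls drawn from the
#' independent healthy test set. Each region's BAG difference is tested
#' with a two-group ANCOVA adjusting for chronological age, sex, MMSE, and
#' education; effect sizes are partial eta-squared; multiple comparisons
#' are handled per (comparison, modality) family with the
#' Benjamini-Yekutieli FDR by default. Clinical associations in
#' significantly accelerated regions use partial correlations controlling
#' for age and sex.
#'
#' @name group_stats
NULL

#' Sample sex-matched controls from the healthy test set
#'
#' Draws, without replacement from HC_test, a control group of the same
#' size as the target patient group with per-sex counts
#' `round(target sex proportion x target size)` (the complementary sex
#' takes the remainder so the total is exact).
#'
#' @param cohort a cohort tibble containing HC_test and the target group.
#' @param target `"BD"` or `"MDD"`.
#' @param seed sampling seed.
#' @return a `matched_controls` list: `target`, `control_ids`, `n`,
#'   `sex_ratio` (achieved female proportion), `seed`.
#' @export
sample_matched_controls <- function(cohort, target = c("BD", "MDD"), seed = 1L) {
  target <- match.arg(target)
  pat <- cohort[cohort$group == target, ]
  pool <- cohort[cohort$group == "HC_test", ]
  n <- nrow(pat)
  assert_that(n > 0, paste0("no subjects in group ", target))
  assert_that(nrow(pool) >= n,
    sprintf("HC_test pool (%d) smaller than target group (%d)", nrow(pool), n),
    class = "regionbag_matching_error")
  nf <- round(mean(pat$sex == "female") * n)
  nm <- n - nf
  pool_f <- pool$subject_id[pool$sex == "female"]
  pool_m <- pool$subject_id[pool$sex == "male"]
  assert_that(length(pool_f) >= nf && length(pool_m) >= nm,
    sprintf(paste0("insufficient HC_test pool per sex: need %d female ",
      "(have %d), %d male (have %d)"), nf, length(pool_f), nm, length(pool_m)),
    class = "regionbag_matching_error")
  ids <- with_seed(mix_seed(seed, 31, match(target, c("BD", "MDD"))), {
    c(
      if (nf > 0) sample(pool_f, nf) else character(),
      if (nm > 0) sample(pool_m, nm) else character()
    )
  })
  structure(
    list(target = target, control_ids = sort(ids), n = n,
      sex_ratio = nf / n, seed = as.integer(seed)),
    class = "matched_controls"
  )
}

#' Two-group ANCOVA on brain-age gap
#'
#' Fits `bag ~ group + covariates` and the covariate-only reduced model on
#' the listwise-complete rows, and derives the group F statistic from the
#' two residual sums of squares:
#' `F = (SS_reduced - SS_full) / (SS_full / (n - p))` with 1 numerator
#' degree of freedom, `partial eta^2 = SS_group / (SS_group + SS_full)`,
#' and covariate-adjusted group means (predictions at the covariate means).
#'
#' @param data tibble with columns `bag`, `group` (exactly two levels:
#'   patient label and `"HC"`/control label), and the covariate columns.
#' @param covariates character vector of covariate column names; `sex` is
#'   coded as a binary indicator.
#' @param patient which `group` level is the patient group; default the
#'   non-HC level.
#' @return one-row tibble: `f`, `p`, `partial_eta2`, `mean_bag_patient`,
#'   `mean_bag_control`, `n`.
#' @export
ancova_bag <- function(data, covariates = c("age", "sex", "mmse", "education"),
                       patient = NULL) {
  assert_that(all(c("bag", "group") %in% names(data)),
    "data needs bag and group columns")
  missing_cov <- setdiff(covariates, names(data))
  assert_that(length(missing_cov) == 0,
    paste0("missing covariate column(s): ", paste(missing_cov, collapse = ", ")),
    class = "regionbag_config_error")
  use <- stats::complete.cases(data[, c("bag", "group", covariates)])
  d <- data[use, , drop = FALSE]
  groups <- sort(unique(d$group))
  assert_that(length(groups) == 2, "need exactly two groups after deletion",
    class = "regionbag_degenerate_error")
  assert_that(nrow(d) >= 8, "fewer than 8 subjects after listwise deletion",
    class = "regionbag_degenerate_error")
  if (is.null(patient)) {
    patient <- setdiff(groups, c("HC", "HC_test", "control"))[1] %||% groups[2]
  }
  d$group_ind <- as.numeric(d$group == patient)
  if ("sex" %in% covariates) d$sex <- as.numeric(d$sex == "female")
  # constant covariates carry no information and would alias the intercept
  constant <- vapply(covariates, function(cv) var(as.numeric(d[[cv]])) == 0,
    logical(1))
  covariates <- covariates[!constant]
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- lm(stats::as.formula(paste("bag ~ group_ind +", rhs_cov)), data = d)
  qrf <- qr(stats::model.matrix(full))
  if (qrf$rank < ncol(stats::model.matrix(full))) {
    cols <- colnames(stats::model.matrix(full))
    dropped <- cols[qrf$pivot[(qrf$rank + 1):length(cols)]]
    abort(paste0("collinear design; rank-deficient column(s): ",
      paste(dropped, collapse = ", ")),
      class = c("regionbag_estimation_error", "regionbag_error"))
  }
  reduced <- lm(stats::as.formula(paste("bag ~", rhs_cov)), data = d)
  ss_full <- sum(stats::residuals(full)^2)
  ss_red <- sum(stats::residuals(reduced)^2)
  ss_group <- ss_red - ss_full
  n <- nrow(d)
  p <- length(coef(full))
  f <- ss_group / (ss_full / (n - p))
  pval <- pf(f, 1, n - p, lower.tail = FALSE)
  eta2 <- if (ss_group + ss_full == 0) 0 else ss_group / (ss_group + ss_full)
  at_means <- d[1, , drop = FALSE]
  for (cv in covariates) at_means[[cv]] <- mean(d[[cv]])
  at_means <- at_means[rep(1, 2), ]
  at_means$group_ind <- c(1, 0)
  adj <- predict(full, newdata = at_means)
  tibble::tibble(
    f = f, p = pval, partial_eta2 = eta2,
    mean_bag_patient = unname(adj[1]), mean_bag_control = unname(adj[2]),
    n = n
  )
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Yekutieli step-up adjustment by default (valid under arbitrary
#' dependence), Benjamini-Hochberg by flag.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param method `"BY"` (default) or `"BH"`.
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvalues, method = c("BY", "BH")) {
  method <- match.arg(method)
  assert_that(all(is.finite(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
    "p-values must lie in [0, 1]", class = "regionbag_validation_error")
  stats::p.adjust(pvalues, method = method)
}

#' Flag regions with significant accelerated aging
#'
#' A region is accelerated when its FDR-adjusted p-value is below `alpha`
#' AND the patient adjusted mean BAG exceeds the control adjusted mean
#' (the acceleration direction); significant decelerations are not
#' flagged.
#'
#' @param results tibble with columns `p_adj`, `mean_bag_patient`,
#'   `mean_bag_control` (e.g. the pipeline's ANCOVA table).
#' @param alpha adjusted-p threshold.
#' @return `results` with a logical `accelerated` column.
#' @export
flag_accelerated <- function(results, alpha = 0.05) {
  dplyr::mutate(results,
    accelerated = .data$p_adj < alpha &
      .data$mean_bag_patient > .data$mean_bag_control)
}

#' Partial correlation controlling for covariates
#'
#' Residualises both variables on an intercept plus the covariates and
#' correlates the residuals; the test statistic is
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `n - 2 - k` degrees of
#' freedom for `k` covariates. With no covariates this reduces to the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data frame (or matrix) of control variables, or
#'   `NULL`.
#' @return one-row tibble: `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- stats::complete.cases(x, y,
    if (is.null(covariates)) rep(TRUE, length(x)) else covariates)
  x <- x[keep]; y <- y[keep]
  k <- 0L
  if (!is.null(covariates)) {
    z <- as.matrix(as.data.frame(covariates)[keep, , drop = FALSE])
    storage.mode(z) <- "double"
    k <- ncol(z)
    zz <- cbind(1, z)
    x <- stats::lm.fit(zz, x)$residuals
    y <- stats::lm.fit(zz, y)$residuals
  }
  n <- length(x)
  assert_that(n >= 5, "need at least 5 complete cases",
    class = "regionbag_degenerate_error")
  assert_that(sd(x) > 0 && sd(y) > 0, "zero residual variance",
    class = "regionbag_degenerate_error")
  r <- cor(x, y)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(r = r, p = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Clinical partial correlations across accelerated regions
#'
#' For every (accelerated region, clinical variable) pair, computes the
#' partial correlation between BAG and the variable controlling for age and
#' sex, with one FDR family over all tested pairs.
#'
#' @param bags prediction tibble with columns `subject_id`, `region`,
#'   `modality`, `bag`.
#' @param cohort cohort tibble supplying the clinical variables and
#'   controls.
#' @param regions character vector of region names to test (typically the
#'   accelerated set).
#' @param variables clinical columns to test.
#' @param controls control columns (default age and sex).
#' @param method FDR method.
#' @return tibble: `region`, `modality`, `variable`, `r`, `p`, `p_adj`,
#'   `n`.
#' @export
clinical_correlations <- function(bags, cohort, regions,
                                  variables = c("ymrs", "hamd21", "hama",
                                    "mmse", "illness_duration"),
                                  controls = c("age", "sex"),
                                  method = "BY") {
  dat <- dplyr::inner_join(bags, cohort, by = "subject_id",
    suffix = c("", ".cohort"))
  if ("sex" %in% controls) dat$sex <- as.numeric(dat$sex == "female")
  grid <- tidyr::expand_grid(region_i = regions, variable = variables)
  res <- purrr::pmap(grid, function(region_i, variable) {
    d <- dat[dat$region == region_i, ]
    out <- tryCatch(
      partial_correlation(d$bag, d[[variable]],
        covariates = d[, controls, drop = FALSE]),
      regionbag_error = function(e) tibble::tibble(r = NA_real_, p = NA_real_,
        n = NA_integer_, df = NA_integer_))
    dplyr::mutate(out, region = region_i,
      modality = d$modality[1] %||% NA_character_, variable = variable)
  })
  res <- dplyr::bind_rows(res)
  ok <- !is.na(res$p)
  res$p_adj <- NA_real_
  res$p_adj[ok] <- fdr_adjust(res$p[ok], method = method)
  res[, c("region", "modality", "variable", "r", "p", "p_adj", "n")]
}
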
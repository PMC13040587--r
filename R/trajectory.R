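#' Per-region brain-age models, bias correction, and BAG
#'
#' Each region of each modality gets its own Gaussian-process age predictor
#' trained on healthy controls, restricted to the region's key voxels and
#' z-scored with training statistics. Fivefold cross-validation (folds
#' stratified by age quintile, seeded) produces one out-of-fold raw
#' prediction per training subject; these fit the linear bias correction
#' that removes the regression-to-the-mean of predicted on chronological
#' age, and the model is then refit on the full training set. The brain-age
#' gap (BAG) is the corrected predicted age minus the chronological age.
#'
#' @name trajectory_model
NULL

# Age-quintile-stratified fold assignment, seeded. Balanced age coverage
# per fold keeps CV predictions stable across the age range.
cv_folds_stratified <- function(ages, n_folds = 5, seed = 1L) {
  n <- length(ages)
  strata <- dplyr::ntile(ages, 5)
  fold <- integer(n)
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

standardize_train <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  bad <- which(!is.finite(sdv) | sdv < 1e-12)
  assert_that(length(bad) == 0,
    paste0("degenerate feature(s) after standardization at column(s): ",
      paste(head(bad, 5), collapse = ", ")),
    class = "regionbag_model_fit_error")
  list(mu = mu, sd = sdv)
}

apply_standardize <- function(x, st) {
  sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
}

#' Fit a region's brain-age model
#'
#' @param region a `region_matrix` restricted to the training controls (or
#'   a plain subjects-by-voxels matrix).
#' @param ages training ages aligned to rows.
#' @param keys a `key_voxel_set` for this region, or an integer vector of
#'   column positions; `NULL` uses all columns.
#' @param n_folds cross-validation folds.
#' @param kernel GPR kernel, `"linear"` (default) or `"rbf"`.
#' @param seed seed for the fold assignment.
#' @return a `region_age_model` containing the refit GPR, the training
#'   standardization statistics, the fold assignment, the out-of-fold raw
#'   training predictions (`cv_prediction` tibble), and — once
#'   [fit_bias_correction()] has been attached — the bias coefficients.
#' @export
fit_region_model <- function(region, ages, keys = NULL, n_folds = 5,
                             kernel = "linear", seed = 1L) {
  if (inherits(region, "region_matrix")) {
    x <- region$x
    meta <- region[c("label", "name", "modality")]
    vox_index <- region$voxel_index
  } else {
    x <- as.matrix(region)
    meta <- list(label = NA_integer_, name = "matrix", modality = NA_character_)
    vox_index <- seq_len(ncol(x)) - 1L
  }
  n <- nrow(x)
  assert_that(n >= 15, "need at least 15 training subjects",
    class = "regionbag_model_fit_error")
  cols <- if (is.null(keys)) seq_len(ncol(x)) else if (inherits(keys, "key_voxel_set"))
    keys$cols else as.integer(keys)
  assert_that(length(cols) > 0, "empty key-voxel set",
    class = "regionbag_model_fit_error")
  x <- x[, cols, drop = FALSE]
  fold <- cv_folds_stratified(ages, n_folds, seed = mix_seed(seed, 7,
    if (is.na(meta$label)) 0L else meta$label))
  raw_cv <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    st_f <- standardize_train(x[tr, , drop = FALSE])
    fit_f <- gpr_fit(apply_standardize(x[tr, , drop = FALSE], st_f), ages[tr],
      kernel = kernel)
    raw_cv[!tr] <- predict(fit_f, apply_standardize(x[!tr, , drop = FALSE], st_f))
  }
  st <- standardize_train(x)
  fit <- gpr_fit(apply_standardize(x, st), ages, kernel = kernel)
  structure(
    list(label = meta$label, name = meta$name, modality = meta$modality,
      key_cols = cols, key_voxels = vox_index[cols],
      standardize = st, gpr = fit, kernel = kernel, fold = fold,
      train_ages = ages,
      cv_prediction = tibble::tibble(row = seq_len(n), age = ages,
        raw = raw_cv, fold = fold),
      bias = NULL, seed = as.integer(seed)),
    class = "region_age_model"
  )
}

#' @export
print.region_age_model <- function(x, ...) {
  cat(sprintf(
    "<region_age_model> %s [%s]: %d key voxels, %d training subjects%s\n",
    x$name, x$modality, length(x$key_cols), length(x$train_ages),
    if (is.null(x$bias)) "" else
      sprintf(", bias alpha=%.3f beta=%.2f", x$bias$alpha, x$bias$beta)))
  invisible(x)
}

#' Predict raw brain age for any population
#'
#' @param model a `region_age_model`.
#' @param region a `region_matrix` (its columns must cover the model's key
#'   voxels) or a plain matrix with the training column layout.
#' @return numeric vector of raw (uncorrected) brain-age predictions.
#' @export
predict_brain_age <- function(model, region) {
  if (inherits(region, "region_matrix")) {
    pos <- match(model$key_voxels, region$voxel_index)
    assert_that(!anyNA(pos),
      paste0("region matrix missing key voxel columns for ", model$name),
      class = "regionbag_schema_error")
    x <- region$x[, pos, drop = FALSE]
  } else {
    x <- as.matrix(region)[, model$key_cols, drop = FALSE]
  }
  predict(model$gpr, apply_standardize(x, model$standardize))
}

#' Fit the linear bias correction
#'
#' Ordinary least squares of raw predicted brain age on chronological age,
#' `raw = alpha * age + beta`, fitted on the training set's out-of-fold
#' predictions (a population independent of every evaluation set).
#'
#' @param raw raw predicted ages.
#' @param ages chronological ages.
#' @return a `bias_correction` list with `alpha`, `beta`, `n`.
#' @export
fit_bias_correction <- function(raw, ages) {
  assert_that(length(raw) == length(ages) && length(ages) >= 3,
    "need at least 3 aligned subjects", class = "regionbag_degenerate_error")
  assert_that(sd(ages) > 0, "ages are constant",
    class = "regionbag_degenerate_error")
  alpha <- cov(ages, raw) / var(ages)
  beta <- mean(raw) - alpha * mean(ages)
  assert_that(abs(alpha) >= 1e-6, "degenerate bias correction: slope ~ 0",
    class = "regionbag_correction_degenerate_error")
  structure(list(alpha = alpha, beta = beta, n = length(ages)),
    class = "bias_correction")
}

#' Apply the bias correction and compute BAG
#'
#' Default `"offset"` form: `corrected = raw + (age - (alpha*age + beta))`,
#' so `BAG = corrected - age = raw - (alpha*age + beta)` exactly. The
#' alternative `"divisive"` form `corrected = (raw - beta)/alpha` is
#' available by flag.
#'
#' @param raw raw predicted ages.
#' @param ages chronological ages.
#' @param bc a `bias_correction`.
#' @param form `"offset"` (default) or `"divisive"`.
#' @return tibble with `age`, `raw`, `corrected`, `bag`.
#' @export
apply_bias_correction <- function(raw, ages, bc, form = c("offset", "divisive")) {
  form <- match.arg(form)
  if (form == "offset") {
    corrected <- raw + (ages - (bc$alpha * ages + bc$beta))
  } else {
    assert_that(abs(bc$alpha) >= 1e-6,
      "divisive correction undefined: slope ~ 0",
      class = "regionbag_correction_degenerate_error")
    corrected <- (raw - bc$beta) / bc$alpha
  }
  tibble::tibble(age = ages, raw = raw, corrected = corrected,
    bag = corrected - ages)
}

#' Model performance before and after bias correction
#'
#' @param predictions tibble with columns `population`, `age`, `raw`,
#'   `corrected` (e.g. rows of the pipeline's prediction table).
#' @return tibble per population: `n`, `mae_raw`, `mae_corrected`,
#'   `r_raw`, `r_corrected` (Pearson; `NA` when undefined, e.g. constant
#'   predictions or fewer than 3 subjects).
#' @export
evaluate_performance <- function(predictions) {
  assert_that(nrow(predictions) > 0, "empty prediction table",
    class = "regionbag_degenerate_error")
  safe_r <- function(a, b) {
    if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }
  predictions |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("region", "modality",
      "population")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae_raw = mean(abs(.data$raw - .data$age)),
      mae_corrected = mean(abs(.data$corrected - .data$age)),
      r_raw = safe_r(.data$raw, .data$age),
      r_corrected = safe_r(.data$corrected, .data$age),
      .groups = "drop"
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a region age model
#'
#' One row per fitted quantity: bias-correction coefficients and GPR
#' hyperparameters.
#'
#' @param x a `region_age_model`.
#' @param ... unused.
#' @return a tibble with `term` and `estimate`.
#' @method tidy region_age_model
#' @export
tidy.region_age_model <- function(x, ...) {
  est <- c(
    bias_alpha = if (is.null(x$bias)) NA_real_ else x$bias$alpha,
    bias_beta = if (is.null(x$bias)) NA_real_ else x$bias$beta,
    gpr_signal_variance = x$gpr$sf2,
    gpr_noise_variance = x$gpr$sn2
  )
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' Glance at a region age model
#'
#' @param x a `region_age_model`.
#' @param ... unused.
#' @return one-row tibble: region, modality, number of key voxels,
#'   training size, and cross-validated raw MAE and Pearson r.
#' @method glance region_age_model
#' @export
glance.region_age_model <- function(x, ...) {
  cv <- x$cv_prediction
  tibble::tibble(
    region = x$name, modality = x$modality,
    n_key_voxels = length(x$key_cols), n_train = length(x$train_ages),
    mae_cv = mean(abs(cv$raw - cv$age)),
    r_cv = if (sd(cv$raw) == 0) NA_real_ else cor(cv$raw, cv$age)
  )
}
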
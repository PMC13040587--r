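#' End-to-end pipeline
#'
#' `run_pipeline()` drives the full analysis on a synthetic study:
#' generate (or accept) cohort and maps, parcellate each modality with its
#' atlas, select key voxels per region on the training controls, fit the
#' per-region GPR age models with fivefold CV, fit and apply the bias
#' correction, compute BAGs for every population, and compare patients
#' with matched controls by ANCOVA with FDR adjustment, flagging and
#' ranking accelerated regions.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param generator a [generator_config()] describing the synthetic study.
#' @param effects an [effect_spec()] of injected accelerations.
#' @param selection a [selection_config()]. Defaults here are desk-scale
#'   iteration counts; pass `selection_config()` for the full
#'   1000-inner / 100-outer procedure.
#' @param comparisons patient groups to compare against matched controls.
#' @param use_modalities subset of `c("GM", "SD", "FA")` to analyse.
#' @param covariates ANCOVA covariates.
#' @param correction_form `"offset"` (default) or `"divisive"`.
#' @param fdr_method `"BY"` (default) or `"BH"`.
#' @param alpha adjusted-p significance threshold.
#' @param kernel GPR kernel.
#' @param n_folds cross-validation folds.
#' @param k_top regions per ranking.
#' @param seed master seed for matching and any generation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            effects = effect_spec(),
                            selection = selection_config(n_inner = 50,
                              n_outer = 5),
                            comparisons = c("BD", "MDD"),
                            use_modalities = c("GM", "SD", "FA"),
                            covariates = c("age", "sex", "mmse", "education"),
                            correction_form = "offset", fdr_method = "BY",
                            alpha = 0.05, kernel = "linear", n_folds = 5,
                            k_top = 20, seed = 1L) {
  structure(
    list(generator = generator, effects = effects, selection = selection,
      comparisons = comparisons, use_modalities = use_modalities,
      covariates = covariates, correction_form = correction_form,
      fdr_method = fdr_method, alpha = alpha, kernel = kernel,
      n_folds = n_folds, k_top = k_top, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

region_subset <- function(region, idx) {
  region$x <- region$x[idx, , drop = FALSE]
  region$subject_id <- region$subject_id[idx]
  region
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-generated study (output of
#'   [generate_study()]); generated from `config$generator` and
#'   `config$effects` when absent.
#' @param out_dir optional directory; when given, all result tables, the
#'   key-voxel lists, and a reproducibility manifest are written there.
#' @return a `bag_run` object: list with `cohort`, `models` (named list of
#'   `region_age_model`), `key_voxels` (summary tibble), `predictions`
#'   (per subject x region x modality), `performance`, `ancova` (per
#'   region x comparison with FDR and acceleration flags), `rankings`,
#'   `matched_controls`, and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
      sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  if (is.null(study)) {
    study <- generate_study(config$generator, config$effects)
    say("generated synthetic study (seed %d)", config$generator$seed)
  }
  cohort <- study$cohort
  train <- which(cohort$group == "HC_train")
  ages_train <- cohort$age[train]
  models <- list()
  predictions <- list()
  key_rows <- list()
  for (m in intersect(config$use_modalities, names(study$maps))) {
    atlas <- study$atlases[[if (m == "FA") "white_matter" else "gray_matter"]]
    regions <- parcellate(study$maps[[m]], atlas, cohort)
    say("parcellated %s into %d regions", m, length(regions))
    for (rg in regions) {
      rg_train <- region_subset(rg, train)
      keys <- build_key_voxel_sets(rg_train, ages_train, config$selection)
      model <- fit_region_model(rg_train, ages_train, keys,
        n_folds = config$n_folds, kernel = config$kernel, seed = config$seed)
      model$bias <- fit_bias_correction(model$cv_prediction$raw, ages_train)
      raw_all <- predict_brain_age(model, rg)
      corr_all <- apply_bias_correction(raw_all, cohort$age, model$bias,
        form = config$correction_form)
      corr_cv <- apply_bias_correction(model$cv_prediction$raw, ages_train,
        model$bias, form = config$correction_form)
      predictions[[paste(m, rg$name)]] <- dplyr::bind_rows(
        dplyr::bind_cols(
          tibble::tibble(subject_id = cohort$subject_id, group = cohort$group,
            population = ifelse(cohort$group == "HC_train", "train_refit",
              cohort$group),
            region = rg$name, modality = m),
          corr_all),
        dplyr::bind_cols(
          tibble::tibble(subject_id = cohort$subject_id[train],
            group = "HC_train", population = "train_cv",
            region = rg$name, modality = m),
          corr_cv)
      )
      key_rows[[paste(m, rg$name)]] <- tibble::tibble(
        region = rg$name, label = rg$label, modality = m,
        n_voxels = ncol(rg$x), n_key = length(keys$cols))
      models[[paste(m, rg$name)]] <- model
    }
    say("fitted %d %s region models", length(regions), m)
  }
  predictions <- dplyr::bind_rows(predictions)
  key_voxels <- dplyr::bind_rows(key_rows)
  performance <- evaluate_performance(
    predictions[predictions$population %in% c("train_cv", "HC_test"), ])
  say("evaluated performance")
  label_map <- key_voxels[!duplicated(paste(key_voxels$modality,
    key_voxels$region)), c("region", "modality", "label")]
  matched <- list()
  ancova <- list()
  for (cmp in config$comparisons) {
    mc <- sample_matched_controls(cohort, cmp, seed = config$seed)
    matched[[cmp]] <- mc
    use_ids <- c(cohort$subject_id[cohort$group == cmp], mc$control_ids)
    dat <- predictions[predictions$subject_id %in% use_ids &
      predictions$population != "train_cv", ]
    dat <- dplyr::inner_join(dat,
      cohort[, c("subject_id", "sex", "mmse", "education")], by = "subject_id")
    dat$group <- ifelse(dat$group == cmp, cmp, "HC")
    res <- dat |>
      dplyr::group_by(.data$region, .data$modality) |>
      dplyr::group_modify(~ ancova_bag(.x, covariates = config$covariates,
        patient = cmp)) |>
      dplyr::ungroup() |>
      dplyr::mutate(comparison = cmp)
    ancova[[cmp]] <- res
    say("ANCOVA for %s vs matched controls (%d regions)", cmp, nrow(res))
  }
  ancova <- dplyr::bind_rows(ancova) |>
    dplyr::group_by(.data$comparison, .data$modality) |>
    dplyr::mutate(p_adj = fdr_adjust(.data$p, method = config$fdr_method)) |>
    dplyr::ungroup() |>
    flag_accelerated(alpha = config$alpha) |>
    dplyr::left_join(label_map, by = c("region", "modality"))
  rankings <- ancova |>
    dplyr::group_by(.data$comparison, .data$modality) |>
    dplyr::group_modify(~ suppressMessages(
      rank_by_effect_size(.x, k = config$k_top, alpha = config$alpha))) |>
    dplyr::ungroup()
  say("ranked accelerated regions")
  run <- structure(
    list(cohort = cohort, models = models, key_voxels = key_voxels,
      predictions = predictions, performance = performance, ancova = ancova,
      rankings = rankings, matched_controls = matched, config = config,
      log = log_lines),
    class = "bag_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.bag_run <- function(x, ...) {
  cat(sprintf(
    "<bag_run> %d region models (%s), %d subjects, %d accelerated region(s)\n",
    length(x$models),
    paste(unique(x$key_voxels$modality), collapse = "/"),
    nrow(x$cohort), sum(x$ancova$accelerated)))
  invisible(x)
}

#' Write a pipeline run's artifacts
#'
#' Writes delimited result tables (predictions, performance, ANCOVA,
#' rankings, key-voxel summary), the per-region key-voxel index lists, a
#' plain-text log with stage timings, and a JSON manifest (full config and
#' seeds) from which [rerun_pipeline()] reproduces the tables bit-exactly.
#'
#' @param run a `bag_run`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$predictions, file.path(out_dir, "predictions.csv"))
  readr::write_csv(run$performance, file.path(out_dir, "performance.csv"))
  readr::write_csv(run$ancova, file.path(out_dir, "ancova.csv"))
  readr::write_csv(run$rankings, file.path(out_dir, "rankings.csv"))
  readr::write_csv(run$key_voxels, file.path(out_dir, "key_voxels.csv"))
  kv_dir <- file.path(out_dir, "key_voxel_sets")
  dir.create(kv_dir, showWarnings = FALSE)
  for (nm in names(run$models)) {
    mod <- run$models[[nm]]
    readr::write_tsv(
      tibble::tibble(voxel_index = mod$key_voxels, column = mod$key_cols),
      file.path(kv_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
  }
  cfg <- run$config
  manifest <- list(
    tool = "regionbag run_pipeline",
    seed = cfg$seed,
    config = list(
      generator = unclass(cfg$generator),
      effects = as.data.frame(cfg$effects),
      selection = unclass(cfg$selection),
      comparisons = cfg$comparisons, use_modalities = cfg$use_modalities,
      covariates = cfg$covariates, correction_form = cfg$correction_form,
      fdr_method = cfg$fdr_method, alpha = cfg$alpha, kernel = cfg$kernel,
      n_folds = cfg$n_folds, k_top = cfg$k_top, seed = cfg$seed
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by [write_run()].
#' @param out_dir output directory for the reproduced artifacts.
#' @return the reproduced `bag_run`.
#' @export
rerun_pipeline <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfgl <- man$config
  eff <- if (length(cfgl$effects) == 0) effect_spec() else
    effect_spec(cfgl$effects$group, cfgl$effects$modality,
      cfgl$effects$region, cfgl$effects$delta)
  cfg <- pipeline_config(
    generator = do.call(generator_config, cfgl$generator),
    effects = eff,
    selection = do.call(selection_config, cfgl$selection),
    comparisons = cfgl$comparisons, use_modalities = cfgl$use_modalities,
    covariates = cfgl$covariates, correction_form = cfgl$correction_form,
    fdr_method = cfgl$fdr_method, alpha = cfgl$alpha, kernel = cfgl$kernel,
    n_folds = cfgl$n_folds, k_top = cfgl$k_top, seed = cfgl$seed
  )
  run_pipeline(cfg, out_dir = out_dir)
}
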
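#' Synthetic cohort generator
#'
#' Generates seeded synthetic cohorts — phenotypes, multimodal voxel maps,
#' and fixture atlases — with the statistical structure the brain-aging
#' analysis assumes: every informative voxel declines linearly with age with
#' additive Gaussian noise, non-informative voxels are pure noise around a
#' baseline, and patient groups can carry an effective-age shift (an extra
#' `delta` years of aging) in chosen regions so that the injected
#' acceleration is directly interpretable as the expected brain-age gap in
#' years.
#'
#' @name synthetic_cohort
NULL

#' Generator configuration
#'
#' Defaults reproduce the study design the package targets: 230 training
#' controls aged 20-84, an independent test set of 110 controls, 110
#' bipolar-disorder and 68 major-depressive-disorder participants. Imaging
#' defaults are desk-scale (10 regions per tissue class, 40 voxels per
#' region on a 24^3 grid); full 90-region / 48-tract atlases are requested
#' via `n_regions_gm` / `n_regions_wm`.
#'
#' @param n_train,n_test,n_bd,n_mdd group sizes.
#' @param age_range age interval (years) ages are drawn uniformly from.
#' @param sex_ratio named list of female proportions per group.
#' @param grid_dim 3-D fixture grid shape.
#' @param n_regions_gm,n_regions_wm regions per tissue class.
#' @param voxels_per_region voxels carrying each region's label.
#' @param informative_fraction proportion of each region's voxels whose
#'   mean depends on age.
#' @param slope_range magnitude range (units/year) of per-voxel age slopes;
#'   slopes are negative (decline). FA slopes and noise are scaled by
#'   `fa_scale` so fractional anisotropy stays in [0, 1].
#' @param noise_sd residual standard deviation of informative voxels (map
#'   units); `noise_sd = 0` makes informative voxels exact affine functions
#'   of effective age.
#' @param pure_noise_sd standard deviation of the non-informative
#'   (pure-noise) voxels around their baseline. Kept separate from
#'   `noise_sd` so that the noiseless-signal limit still contains genuine
#'   noise voxels rather than constants.
#' @param fa_scale multiplicative scale applied to FA slopes and noise.
#' @param missing_rate probability a clinical covariate value is missing.
#' @param seed master seed; every derived draw is a deterministic function
#'   of it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_train = 230, n_test = 110, n_bd = 110,
                             n_mdd = 68, age_range = c(20, 84),
                             sex_ratio = list(HC_train = 0.5, HC_test = 0.5,
                               BD = 0.5, MDD = 0.5),
                             grid_dim = c(24, 24, 24),
                             n_regions_gm = 10, n_regions_wm = 10,
                             voxels_per_region = 40,
                             informative_fraction = 0.5,
                             slope_range = c(0.015, 0.035),
                             noise_sd = 0.5, pure_noise_sd = 0.5,
                             fa_scale = 0.005,
                             missing_rate = 0, seed = 1L) {
  cfg <- list(
    n_train = n_train, n_test = n_test, n_bd = n_bd, n_mdd = n_mdd,
    age_range = age_range, sex_ratio = sex_ratio, grid_dim = grid_dim,
    n_regions_gm = n_regions_gm, n_regions_wm = n_regions_wm,
    voxels_per_region = voxels_per_region,
    informative_fraction = informative_fraction,
    slope_range = slope_range, noise_sd = noise_sd,
    pure_noise_sd = pure_noise_sd, fa_scale = fa_scale,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  assert_that(all(c(n_train, n_test, n_bd, n_mdd) > 0),
    "group sizes must be positive", class = "regionbag_config_error")
  assert_that(informative_fraction >= 0 && informative_fraction <= 1,
    "informative_fraction must lie in [0, 1]",
    class = "regionbag_config_error")
  assert_that(noise_sd >= 0 && pure_noise_sd >= 0 &&
      missing_rate >= 0 && missing_rate <= 1,
    "invalid noise_sd or missing_rate", class = "regionbag_config_error")
  needed <- (n_regions_gm + n_regions_wm) * voxels_per_region
  assert_that(needed <= prod(grid_dim),
    sprintf("grid too small: %d labelled voxels needed, %d cells available",
      needed, prod(grid_dim)),
    class = "regionbag_config_error")
  structure(cfg, class = "generator_config")
}

#' Group-specific acceleration effects
#'
#' Declares which regions of which modality carry accelerated aging in
#' which patient group, as an effective-age shift of `delta` years. All
#' modality effects are declines (reduced gray-matter intensity, reduced
#' BOLD-signal variability, reduced fractional anisotropy), which the
#' generator realises through the negative per-voxel age slopes.
#'
#' @param group character vector, `"BD"` or `"MDD"`.
#' @param modality character vector, `"GM"`, `"SD"`, or `"FA"`.
#' @param region region names (recycled against group/modality).
#' @param delta non-negative acceleration in years.
#' @return an `effect_spec` tibble with one row per affected
#'   (group, modality, region).
#' @export
effect_spec <- function(group = character(), modality = character(),
                        region = character(), delta = numeric()) {
  out <- tibble::tibble(group = group, modality = modality,
    region = region, delta = delta)
  assert_that(all(out$delta >= 0), "delta must be non-negative",
    class = "regionbag_config_error")
  assert_that(all(out$group %in% c("BD", "MDD")),
    "effect groups must be BD or MDD", class = "regionbag_config_error")
  assert_that(all(out$modality %in% modalities),
    "unknown modality in effect_spec", class = "regionbag_config_error")
  class(out) <- c("effect_spec", class(out))
  out
}

#' Generate a synthetic phenotype cohort
#'
#' Draws ages uniformly over the configured range, assigns sex to match the
#' per-group ratios exactly (up to rounding), and draws clinical covariates
#' from documented distributions: MMSE ~ round(N(28, 1.5)) clipped to
#' [10, 30], education ~ round(N(14, 3)) clipped to [6, 22] years, YMRS
#' (BD only) ~ round(N(8, 4)) clipped at 0, HAM-D-21 and HAM-A (patients)
#' ~ round(N(10, 5)) clipped at 0, illness duration uniform over 1-25 years
#' (BD) or 1-10 years (MDD). Covariates are generated independently of the
#' voxel maps. Deterministic under the config seed.
#'
#' @param config a [generator_config()].
#' @return a validated cohort tibble with a `provenance` attribute.
#' @export
generate_cohort <- function(config) {
  counts <- c(HC_train = config$n_train, HC_test = config$n_test,
    BD = config$n_bd, MDD = config$n_mdd)
  with_seed(mix_seed(config$seed, 101), {
    rows <- purrr::map(names(counts), function(g) {
      n <- counts[[g]]
      nf <- round(config$sex_ratio[[g]] * n)
      sex <- sample(c(rep("female", nf), rep("male", n - nf)))
      age <- runif(n, config$age_range[1], config$age_range[2])
      clip_round <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))
      tibble::tibble(
        subject_id = sprintf("%s_%03d", g, seq_len(n)),
        age = age, sex = sex, group = g,
        mmse = clip_round(rnorm(n, 28, 1.5), 10, 30),
        education = clip_round(rnorm(n, 14, 3), 6, 22),
        ymrs = if (g == "BD") clip_round(rnorm(n, 8, 4), 0, 60) else NA_real_,
        hamd21 = if (g %in% c("BD", "MDD"))
          clip_round(rnorm(n, 10, 5), 0, 52) else NA_real_,
        hama = if (g %in% c("BD", "MDD"))
          clip_round(rnorm(n, 10, 5), 0, 56) else NA_real_,
        illness_duration = if (g == "BD") runif(n, 1, 25)
          else if (g == "MDD") runif(n, 1, 10) else NA_real_
      )
    })
    cohort <- dplyr::bind_rows(rows)
    if (config$missing_rate > 0) {
      for (col in c("mmse", "education", "ymrs", "hamd21", "hama",
        "illness_duration")) {
        drop <- runif(nrow(cohort)) < config$missing_rate
        cohort[[col]][drop] <- NA_real_
      }
    }
    cohort <- validate_cohort(cohort, age_range = config$age_range)
    attr(cohort, "provenance") <- list(kind = "synthetic", seed = config$seed)
    cohort
  })
}

#' Build a fixture label atlas
#'
#' Lays regions out as consecutive runs of `voxels_per_region` cells in
#' flat (column-major) grid order, starting at `offset`. When the region
#' count matches the real atlases (90 gray-matter regions, 48 white-matter
#' tracts) the bundled AAL / JHU-ICBM label tables supply the names;
#' otherwise synthetic paired names (`G01.L`, `G01.R`, ...) are used.
#'
#' @param config a [generator_config()].
#' @param tissue `"gray_matter"` or `"white_matter"`.
#' @param offset first flat cell (0-based) to label; lets the white-matter
#'   fixture atlas occupy cells disjoint from the gray-matter one when both
#'   live on one grid.
#' @return a `label_atlas`.
#' @export
build_fixture_atlas <- function(config, tissue = c("gray_matter", "white_matter"),
                                offset = 0L) {
  tissue <- match.arg(tissue)
  n_reg <- if (tissue == "gray_matter") config$n_regions_gm else config$n_regions_wm
  v <- config$voxels_per_region
  assert_that(offset + n_reg * v <= prod(config$grid_dim),
    "grid too small for requested atlas", class = "regionbag_config_error")
  lab <- integer(prod(config$grid_dim))
  for (r in seq_len(n_reg)) {
    lab[offset + (r - 1L) * v + seq_len(v)] <- r
  }
  nm <- if (tissue == "gray_matter" && n_reg == 90) {
    aal_labels()$code
  } else if (tissue == "white_matter" && n_reg == 48) {
    jhu_labels()$code
  } else {
    prefix <- if (tissue == "gray_matter") "G" else "W"
    paste0(prefix, sprintf("%02d", ceiling(seq_len(n_reg) / 2)),
      c(".L", ".R")[(seq_len(n_reg) - 1L) %% 2L + 1L])
  }
  label_atlas(array(lab, dim = config$grid_dim),
    region_names = stats::setNames(nm[seq_len(n_reg)], seq_len(n_reg)),
    tissue = tissue)
}

#' Generate multimodal voxel maps for a cohort
#'
#' For every region and modality, a seeded fraction of voxels is
#' age-informative: voxel `v` of subject `s` takes the value
#' `b0_v + b1_v * effective_age_s + e`, with `b1_v < 0` (decline),
#' `e ~ N(0, noise_sd)`, and `effective_age = age + delta` for patients in
#' regions the [effect_spec()] marks as accelerated (else the chronological
#' age). Non-informative voxels are pure noise around their baseline with
#' standard deviation `pure_noise_sd`.
#' Gray-matter and SD maps share the gray-matter fixture atlas; FA maps use
#' the white-matter atlas with slopes and noise scaled by `fa_scale` and
#' values clipped to [0, 1].
#'
#' @param cohort a cohort tibble.
#' @param config a [generator_config()].
#' @param effects an [effect_spec()] (default: no acceleration anywhere).
#' @return a list with `atlases` (per tissue class), `maps` (a
#'   `voxel_map_set` per modality), and `truth` (a tibble of per-voxel
#'   generating parameters, for diagnostics and tests).
#' @export
generate_region_voxels <- function(cohort, config, effects = effect_spec()) {
  atl_gm <- build_fixture_atlas(config, "gray_matter")
  atl_wm <- build_fixture_atlas(config, "white_matter",
    offset = config$n_regions_gm * config$voxels_per_region)
  atlases <- list(gray_matter = atl_gm, white_matter = atl_wm)
  for (i in seq_len(nrow(effects))) {
    atl <- if (effects$modality[i] == "FA") atl_wm else atl_gm
    assert_that(effects$region[i] %in% atl$region_names,
      paste0("effect region not in atlas: ", effects$region[i]),
      class = "regionbag_config_error")
  }
  n <- nrow(cohort)
  truth <- list()
  maps <- list()
  for (m in modalities) {
    atl <- if (m == "FA") atl_wm else atl_gm
    scale_m <- if (m == "FA") config$fa_scale else 1
    b0_lo <- if (m == "FA") 0.75 else 4
    b0_hi <- if (m == "FA") 0.95 else 8
    data <- matrix(0, n, prod(config$grid_dim))
    lab_vec <- as.vector(atl$labels)
    for (lb in names(atl$region_names)) {
      rname <- unname(atl$region_names[[lb]])
      idx <- which(lab_vec == as.integer(lb))
      v <- length(idx)
      block <- with_seed(mix_seed(config$seed, match(m, modalities), as.integer(lb)), {
        n_inf <- round(config$informative_fraction * v)
        inf <- sort(sample.int(v, n_inf))
        b0 <- runif(v, b0_lo, b0_hi)
        b1 <- numeric(v)
        b1[inf] <- -runif(n_inf, config$slope_range[1], config$slope_range[2]) *
          scale_m
        eff_age <- cohort$age
        hit <- effects[effects$modality == m & effects$region == rname, ,
          drop = FALSE]
        for (j in seq_len(nrow(hit))) {
          sel <- cohort$group == hit$group[j]
          eff_age[sel] <- eff_age[sel] + hit$delta[j]
        }
        x <- matrix(b0, n, v, byrow = TRUE) + outer(eff_age, b1)
        sd_col <- ifelse(seq_len(v) %in% inf, config$noise_sd,
          config$pure_noise_sd) * scale_m
        if (any(sd_col > 0)) {
          eps <- matrix(rnorm(n * v), n, v)
          x <- x + sweep(eps, 2, sd_col, "*")
        }
        list(x = x, b0 = b0, b1 = b1, inf = inf)
      })
      data[, idx] <- block$x
      truth[[paste(m, rname)]] <- tibble::tibble(
        modality = m, region = rname, label = as.integer(lb),
        voxel_index = idx - 1L, b0 = block$b0, b1 = block$b1,
        informative = seq_len(v) %in% block$inf
      )
    }
    if (m == "FA") data <- pmin(pmax(data, 0), 1)
    maps[[m]] <- voxel_map_set(data, cohort$subject_id, m, config$grid_dim)
  }
  list(atlases = atlases, maps = maps, truth = dplyr::bind_rows(truth))
}

#' Generate a full synthetic study
#'
#' Convenience wrapper: [generate_cohort()] then [generate_region_voxels()].
#'
#' @inheritParams generate_region_voxels
#' @return a list with `cohort`, `atlases`, `maps`, `truth`, `config`,
#'   `effects`.
#' @export
generate_study <- function(config, effects = effect_spec()) {
  cohort <- generate_cohort(config)
  sim <- generate_region_voxels(cohort, config, effects)
  c(list(cohort = cohort, config = config, effects = effects), sim)
}

#' Write a generated study to disk as a fixture set
#'
#' Writes one NIfTI volume per subject and modality, the atlas volumes, the
#' phenotype table, and a JSON manifest recording the config, effects, and
#' seed. Re-running the generator from the manifest (see
#' [replay_fixture_set()]) reproduces every file bit-exactly.
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_fixture_set <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE))
  write_cohort_table(study$cohort, file.path(dir, "phenotypes.csv"))
  for (tc in names(study$atlases)) {
    write_volume(study$atlases[[tc]], file.path(dir, paste0("atlas_", tc, ".nii.gz")))
  }
  for (m in names(study$maps)) {
    set <- study$maps[[m]]
    for (i in seq_along(set$subject_id)) {
      vm <- voxel_map(array(set$data[i, ], dim = set$grid_dim),
        set$subject_id[i], m)
      write_volume(vm, file.path(dir,
        sprintf("%s_%s.nii.gz", m, set$subject_id[i])))
    }
  }
  manifest <- list(
    generator = "regionbag synthetic cohort",
    seed = study$config$seed,
    config = unclass(study$config),
    effects = as.data.frame(study$effects)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  ok <- TRUE
  invisible(mpath)
}

#' Regenerate a fixture set from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_fixture_set()].
#' @param dir output directory.
#' @return path of the rewritten manifest, invisibly.
#' @export
replay_fixture_set <- function(manifest_path, dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(generator_config, man$config[setdiff(names(man$config), NULL)])
  eff <- if (length(man$effects) == 0) effect_spec() else
    effect_spec(man$effects$group, man$effects$modality, man$effects$region,
      man$effects$delta)
  write_fixture_set(generate_study(cfg, eff), dir)
}
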
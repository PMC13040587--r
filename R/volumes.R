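#' Voxel maps, label atlases, and parcellation
#'
#' Volumes are plain 3-D numeric arrays carrying `subject_id` and `modality`
#' attributes (`voxel_map`) or integer label grids with a label-to-name map
#' (`label_atlas`). Voxel coordinates are referred to throughout by 0-based
#' flat indices in column-major (grid-major) order, so index `i` addresses
#' `array[i + 1]` of the flattened grid.
#'
#' @name volumes
NULL

modalities <- c("GM", "SD", "FA")

#' Construct a voxel map
#'
#' @param values 3-D numeric array.
#' @param subject_id subject identifier.
#' @param modality one of `"GM"` (gray-matter intensity), `"SD"`
#'   (voxel-wise standard deviation of the resting-state fMRI signal), or
#'   `"FA"` (fractional anisotropy).
#' @return a `voxel_map` (numeric array with metadata attributes).
#' @export
voxel_map <- function(values, subject_id, modality) {
  assert_that(length(dim(values)) == 3, "values must be a 3-D array")
  assert_that(modality %in% modalities,
    paste0("unknown modality: ", modality))
  assert_that(all(is.finite(values)), "voxel values must be finite",
    class = "regionbag_validation_error")
  if (modality == "FA") {
    assert_that(all(values >= 0 & values <= 1),
      "FA values must lie in [0, 1]", class = "regionbag_validation_error")
  }
  structure(values, subject_id = subject_id, modality = modality,
    class = c("voxel_map", "array"))
}

#' Construct a label atlas
#'
#' @param labels 3-D integer array; 0 is background.
#' @param region_names named character vector mapping label (as character)
#'   to region name. Defaults to `"region_<label>"`.
#' @param tissue `"gray_matter"` or `"white_matter"`.
#' @param laterality optional named character vector per label with values
#'   `"left"`, `"right"`, or `"midline"`; inferred from `.L`/`.R` name
#'   suffixes when absent.
#' @return a `label_atlas` object.
#' @export
label_atlas <- function(labels, region_names = NULL,
                        tissue = c("gray_matter", "white_matter"),
                        laterality = NULL) {
  tissue <- match.arg(tissue)
  assert_that(length(dim(labels)) == 3, "labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  assert_that(all(present > 0), "negative labels are not allowed")
  if (is.null(region_names)) {
    region_names <- stats::setNames(paste0("region_", present), present)
  }
  assert_that(all(as.character(present) %in% names(region_names)),
    "region_names must cover every non-background label")
  region_names <- region_names[as.character(present)]
  if (is.null(laterality)) {
    laterality <- ifelse(grepl("\\.L$", region_names), "left",
      ifelse(grepl("\\.R$", region_names), "right", "midline"))
    names(laterality) <- names(region_names)
  }
  structure(
    list(labels = labels, region_names = region_names,
      tissue = tissue, laterality = laterality),
    class = "label_atlas"
  )
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s, %d regions, grid %s\n",
    x$tissue, n_regions(x), paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Number of non-background regions in an atlas
#' @param atlas a `label_atlas`.
#' @export
n_regions <- function(atlas) length(atlas$region_names)

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file. With `as = "atlas"` the volume is coerced
#' to integer labels and wrapped as a [label_atlas()].
#'
#' @param path file path.
#' @param as `"map"` or `"atlas"`.
#' @param subject_id,modality metadata for `as = "map"`.
#' @param ... passed on to [label_atlas()] for `as = "atlas"`.
#' @return a `voxel_map` or `label_atlas`.
#' @export
read_volume <- function(path, as = c("map", "atlas"), subject_id = NA_character_,
                        modality = "GM", ...) {
  as <- match.arg(as)
  assert_that(file.exists(path), paste0("no such file: ", path),
    class = "regionbag_config_error")
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (as == "atlas") {
    label_atlas(array(as.integer(round(arr)), dim = dim(arr)), ...)
  } else {
    voxel_map(arr, subject_id = subject_id, modality = modality)
  }
}

#' Write a volume as NIfTI-1
#'
#' @param x a `voxel_map`, `label_atlas`, or 3-D array.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "label_atlas")) x$labels else unclass(x)
  attributes(arr) <- list(dim = dim(arr))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Voxel-wise standard deviation of a 4-D time series
#'
#' Collapses a 4-D resting-state series (x, y, z, time) to a 3-D map of the
#' per-voxel sample standard deviation (divisor n - 1), the BOLD-variability
#' feature used by the SD modality.
#'
#' @param series 4-D numeric array with time as the last dimension.
#' @param subject_id subject identifier for the resulting map.
#' @return a `voxel_map` with modality `"SD"`.
#' @export
voxelwise_sd <- function(series, subject_id = NA_character_) {
  assert_that(length(dim(series)) == 4, "series must be a 4-D array")
  nt <- dim(series)[4]
  assert_that(nt >= 2, "need at least 2 time points for a standard deviation",
    class = "regionbag_degenerate_error")
  d <- dim(series)[1:3]
  m <- matrix(series, nrow = prod(d), ncol = nt)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (nt - 1))
  voxel_map(array(s, dim = d), subject_id = subject_id, modality = "SD")
}

# Internal dense container: all subjects' maps of one modality as a
# subjects x voxels matrix over the flattened grid. Cheap to parcellate and
# cheap to generate; individual voxel_map objects convert in and out.
voxel_map_set <- function(data, subject_id, modality, grid_dim) {
  assert_that(nrow(data) == length(subject_id),
    "one row per subject required")
  assert_that(ncol(data) == prod(grid_dim), "data must cover the full grid")
  structure(
    list(data = data, subject_id = subject_id, modality = modality,
      grid_dim = as.integer(grid_dim)),
    class = "voxel_map_set"
  )
}

#' Stack per-subject voxel maps into a map set
#'
#' @param maps list of `voxel_map` objects, one per subject, sharing grid
#'   shape and modality.
#' @return a `voxel_map_set` used by [parcellate()].
#' @export
stack_voxel_maps <- function(maps) {
  assert_that(length(maps) > 0, "no maps supplied")
  dims <- unique(lapply(maps, dim))
  assert_that(length(dims) == 1, "maps disagree on grid shape",
    class = "regionbag_alignment_error")
  mods <- unique(vapply(maps, attr, "", "modality"))
  assert_that(length(mods) == 1, "maps disagree on modality")
  ids <- vapply(maps, attr, "", "subject_id")
  data <- do.call(rbind, lapply(maps, as.vector))
  voxel_map_set(data, ids, mods, dims[[1]])
}

#' Parcellate voxel maps into per-region subject-by-voxel matrices
#'
#' Splits the flattened grid by atlas label and extracts, for each region,
#' the subjects-by-voxels feature block. The voxel index lists of all
#' regions plus the background partition the grid exactly.
#'
#' @param maps a `voxel_map_set` (see [stack_voxel_maps()]) or a list of
#'   `voxel_map` objects.
#' @param atlas a `label_atlas` on the same grid.
#' @param cohort optional cohort tibble; when supplied, rows are checked and
#'   reordered to the cohort's subject ordering, and subjects missing a map
#'   raise an error naming them.
#' @return a named list of `region_matrix` objects (one per label, named by
#'   region name), each with fields `label`, `name`, `modality`,
#'   `subject_id`, `x` (subjects x voxels matrix), and `voxel_index`
#'   (0-based flat grid indices of its columns).
#' @export
parcellate <- function(maps, atlas, cohort = NULL) {
  if (!inherits(maps, "voxel_map_set")) maps <- stack_voxel_maps(maps)
  assert_that(identical(as.integer(maps$grid_dim), as.integer(dim(atlas$labels))),
    "maps and atlas disagree on grid shape",
    class = "regionbag_alignment_error")
  if (!is.null(cohort)) {
    missing_ids <- setdiff(cohort$subject_id, maps$subject_id)
    assert_that(length(missing_ids) == 0,
      paste0("subjects missing a ", maps$modality, " map: ",
        paste(missing_ids, collapse = ", ")),
      class = "regionbag_incomplete_cohort_error")
    ord <- match(cohort$subject_id, maps$subject_id)
    maps <- voxel_map_set(maps$data[ord, , drop = FALSE],
      maps$subject_id[ord], maps$modality, maps$grid_dim)
  }
  lab <- as.vector(atlas$labels)
  out <- lapply(names(atlas$region_names), function(lb) {
    idx <- which(lab == as.integer(lb))
    structure(
      list(
        label = as.integer(lb),
        name = unname(atlas$region_names[[lb]]),
        modality = maps$modality,
        subject_id = maps$subject_id,
        x = maps$data[, idx, drop = FALSE],
        voxel_index = idx - 1L
      ),
      class = "region_matrix"
    )
  })
  names(out) <- unname(atlas$region_names)
  out
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf("<region_matrix> %s [%s] label %d: %d subjects x %d voxels\n",
    x$name, x$modality, x$label, nrow(x$x), ncol(x$x)))
  invisible(x)
}
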
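#' Key-voxel selection by repeated subsampled age correlation
#'
#' For each region, voxels that track chronological age are identified by a
#' two-level resampling scheme: in each inner iteration a random 70% of the
#' training participants is drawn, the Pearson correlation of every voxel
#' with age is computed on that subsample, and the top half of voxels by
#' correlation magnitude is kept; the voxels surviving all (or a configured
#' fraction of) inner iterations form one consensus set. The whole procedure
#' is repeated `n_outer` times with independent seeded streams, and the
#' union of the outer consensus sets is the region's key-voxel set.
#'
#' @name feature_selection
NULL

#' Selection configuration
#'
#' @param subsample_fraction fraction of training participants drawn
#'   (without replacement) per inner iteration.
#' @param n_inner inner iterations per consensus set.
#' @param top_fraction fraction of rankable voxels retained per iteration.
#' @param n_outer number of consensus sets whose union forms the key set.
#' @param consensus_quantile fraction of inner iterations a voxel must
#'   appear in; 1.0 is the strict intersection. An empty strict
#'   intersection falls back to 0.9 with a warning.
#' @param signed rank by signed correlation instead of magnitude. Default
#'   `FALSE`: age effects in these data are declines (negative
#'   correlations), which signed ranking would discard.
#' @param seed master seed; per-(outer, inner) substreams are derived from
#'   it.
#' @return a `selection_config` list.
#' @export
selection_config <- function(subsample_fraction = 0.70, n_inner = 1000,
                             top_fraction = 0.50, n_outer = 100,
                             consensus_quantile = 1.0, signed = FALSE,
                             seed = 1L) {
  assert_that(subsample_fraction > 0 && subsample_fraction <= 1 &&
      top_fraction > 0 && top_fraction <= 1 &&
      consensus_quantile > 0 && consensus_quantile <= 1,
    "fractions must lie in (0, 1]", class = "regionbag_config_error")
  assert_that(n_inner >= 1 && n_outer >= 1, "iteration counts must be positive",
    class = "regionbag_config_error")
  structure(
    list(subsample_fraction = subsample_fraction, n_inner = n_inner,
      top_fraction = top_fraction, n_outer = n_outer,
      consensus_quantile = consensus_quantile, signed = signed,
      seed = as.integer(seed)),
    class = "selection_config"
  )
}

#' Per-voxel Pearson correlation with age
#'
#' @param x subjects-by-voxels numeric matrix (or a `region_matrix`).
#' @param ages chronological ages aligned to the rows of `x`.
#' @return numeric vector of Pearson correlations, one per voxel; voxels
#'   with (numerically) zero variance are `NA` and excluded from ranking
#'   downstream.
#' @export
voxel_age_correlation <- function(x, ages) {
  if (inherits(x, "region_matrix")) x <- x$x
  n <- nrow(x)
  assert_that(n >= 3, "need at least 3 subjects",
    class = "regionbag_degenerate_error")
  assert_that(length(ages) == n, "ages must align with matrix rows")
  a <- ages - mean(ages)
  ssa <- sum(a^2)
  assert_that(ssa > 0, "ages are constant",
    class = "regionbag_degenerate_error")
  mu <- colMeans(x)
  xc <- x - rep(mu, each = n)
  ssx <- colSums(xc^2)
  r <- as.vector(crossprod(a, xc)) / sqrt(ssa * ssx)
  scale2 <- colMeans(x^2)
  degenerate <- ssx <= 1e-12 * pmax(scale2, 1) * n
  r[degenerate] <- NA_real_
  r
}

#' One inner selection iteration
#'
#' Draws a seeded subsample of participants without replacement, correlates
#' every voxel with age on it, and returns the top `top_fraction` of
#' rankable voxels (by |r|, or signed r when configured), i.e.
#' `ceiling(top_fraction * n_rankable)` voxels. Exact ties at the cutoff are
#' broken deterministically in favour of the lower voxel column index.
#'
#' @param x subjects-by-voxels matrix (or `region_matrix`).
#' @param ages ages aligned to rows.
#' @param config a [selection_config()].
#' @param iter_seed seed for this iteration's subsample.
#' @return sorted integer vector of selected voxel column positions.
#' @export
select_iteration_set <- function(x, ages, config, iter_seed) {
  if (inherits(x, "region_matrix")) x <- x$x
  n <- nrow(x)
  m <- max(3L, round(config$subsample_fraction * n))
  assert_that(m <= n, "subsample larger than cohort",
    class = "regionbag_config_error")
  idx <- with_seed(iter_seed, sample.int(n, m))
  r <- voxel_age_correlation(x[idx, , drop = FALSE], ages[idx])
  crit <- if (config$signed) r else abs(r)
  rankable <- which(!is.na(crit))
  assert_that(length(rankable) > 0, "all voxels degenerate in subsample",
    class = "regionbag_empty_set_error")
  k <- ceiling(config$top_fraction * length(rankable))
  ord <- rankable[order(-crit[rankable], rankable)]
  sort(ord[seq_len(k)])
}

#' Consensus over inner iteration sets
#'
#' With `consensus_quantile = 1` this is the strict intersection of all
#' inner sets; otherwise voxels present in at least
#' `ceiling(consensus_quantile * n_inner)` sets survive. An empty strict
#' intersection triggers the documented fallback to a 0.9 consensus with a
#' warning; a set that is empty even then is returned empty (the caller
#' flags the region unselectable).
#'
#' @param sets list of integer voxel-position vectors.
#' @param config a [selection_config()].
#' @return sorted integer vector of consensus voxel positions, with
#'   attribute `fallback = TRUE` when the relaxation was used.
#' @export
intersect_iterations <- function(sets, config) {
  assert_that(length(sets) >= 1, "need at least one iteration set")
  counts <- table(unlist(sets))
  pick <- function(q) {
    thr <- ceiling(q * length(sets))
    sort(as.integer(names(counts)[counts >= thr]))
  }
  out <- pick(config$consensus_quantile)
  if (length(out) == 0 && config$consensus_quantile == 1) {
    warn("strict intersection empty; falling back to 0.9 consensus",
      class = "regionbag_consensus_fallback")
    out <- pick(0.9)
    attr(out, "fallback") <- TRUE
  }
  out
}

#' Build a region's key-voxel set
#'
#' Runs the inner consensus procedure `n_outer` times under independent
#' seeded substreams and takes the union of the consensus sets as the key
#' features, recording how many outer sets each voxel appeared in.
#'
#' @param region a `region_matrix` (training subjects only) or a plain
#'   subjects-by-voxels matrix.
#' @param ages training ages aligned to the rows.
#' @param config a [selection_config()].
#' @return a `key_voxel_set`: list with `label`, `name`, `modality`,
#'   `cols` (selected column positions), `voxels` (0-based flat grid
#'   indices), `frequency` (outer-set counts per selected voxel), and the
#'   config snapshot.
#' @export
build_key_voxel_sets <- function(region, ages, config = selection_config()) {
  if (inherits(region, "region_matrix")) {
    x <- region$x
    meta <- region[c("label", "name", "modality")]
    vox_index <- region$voxel_index
  } else {
    x <- region
    meta <- list(label = NA_integer_, name = "matrix", modality = NA_character_)
    vox_index <- seq_len(ncol(x)) - 1L
  }
  tag <- if (is.na(meta$label)) 0L else meta$label
  mtag <- if (is.na(meta$modality)) 0L else match(meta$modality, modalities)
  outer_sets <- lapply(seq_len(config$n_outer), function(o) {
    inner <- lapply(seq_len(config$n_inner), function(i) {
      select_iteration_set(x, ages, config,
        iter_seed = mix_seed(config$seed, mtag, tag, o, i))
    })
    withCallingHandlers(
      intersect_iterations(inner, config),
      regionbag_consensus_fallback = function(w) {
        invokeRestart("muffleWarning")
      }
    )
  })
  counts <- table(unlist(outer_sets))
  assert_that(length(counts) > 0,
    paste0("region unselectable (all consensus sets empty): ", meta$name),
    class = "regionbag_unselectable_error")
  cols <- sort(as.integer(names(counts)))
  structure(
    list(label = meta$label, name = meta$name, modality = meta$modality,
      cols = cols, voxels = vox_index[cols],
      frequency = as.integer(counts[as.character(cols)]),
      config = config),
    class = "key_voxel_set"
  )
}

#' @export
print.key_voxel_set <- function(x, ...) {
  cat(sprintf("<key_voxel_set> %s [%s]: %d voxels (n_outer = %d)\n",
    x$name, x$modality, length(x$cols), x$config$n_outer))
  invisible(x)
}

#' Write / read a key-voxel set as plain text
#'
#' Persists the selected 0-based flat voxel indices and outer-set
#' frequencies as a tab-separated table with a JSON config sidecar.
#'
#' @param keys a `key_voxel_set`.
#' @param path output path for the index table; the config snapshot goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_key_voxel_set <- function(keys, path) {
  readr::write_tsv(
    tibble::tibble(voxel_index = keys$voxels, column = keys$cols,
      frequency = keys$frequency),
    path)
  jsonlite::write_json(
    c(keys[c("label", "name", "modality")], unclass(keys$config)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
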
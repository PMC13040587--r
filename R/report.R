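#' Region rankings and common/distinct set logic
#'
#' After FDR adjustment, accelerated regions are ranked by partial
#' eta-squared to extract the top-k regions per comparison and modality,
#' and top-k lists from different comparisons are intersected to separate
#' shared from disorder-specific regions. Region names use the standard
#' AAL short codes (e.g. `SFGdor.L`) and JHU-ICBM tract codes; shorthand
#' entries (`<code>.B` for bilateral pairs, `CC` for the corpus callosum)
#' are expanded mechanically.
#'
#' @name reporting
NULL

extdata <- function(file) {
  system.file("extdata", file, package = "regionbag", mustWork = TRUE)
}

#' Bundled AAL 90-region gray-matter label table
#'
#' @return tibble with `label` (1-90), `code` (e.g. `SFGdor.L`), `name`,
#'   `laterality`.
#' @export
aal_labels <- function() {
  readr::read_csv(extdata("aal90_labels.csv"), show_col_types = FALSE)
}

#' Bundled JHU-ICBM 48-tract white-matter label table
#'
#' @return tibble with `label` (1-48), `code` (e.g. `CST.L`), `name`,
#'   `laterality`.
#' @export
jhu_labels <- function() {
  readr::read_csv(extdata("jhu48_labels.csv"), show_col_types = FALSE)
}

#' Reference top-20 accelerated-region lists
#'
#' The top-20 gray-matter regions and fractional-anisotropy tracts with
#' the most significant accelerated aging reported for BD and MDD cohorts,
#' transcribed in shorthand form (bilateral pairs as `<code>.B`, the
#' corpus callosum as `CC`). Used as fixed inputs for the common/distinct
#' set logic.
#'
#' @param comparison `"BD"` or `"MDD"`, or `NULL` for all rows.
#' @param modality `"GM"` or `"FA"`, or `NULL` for all rows.
#' @return tibble with `comparison`, `modality`, `code`.
#' @export
reference_top20 <- function(comparison = NULL, modality = NULL) {
  x <- readr::read_csv(extdata("top20_reference_lists.csv"),
    show_col_types = FALSE)
  if (!is.null(comparison)) x <- x[x$comparison == comparison, ]
  if (!is.null(modality)) x <- x[x$modality == modality, ]
  x
}

#' Expand bilateral and corpus-callosum shorthand
#'
#' `<code>.B` expands to `<code>.L` and `<code>.R`; `CC` expands to the
#' genu, body, and splenium of the corpus callosum (`GCC`, `BCC`, `SCC`);
#' every other code passes through unchanged. Order is preserved.
#'
#' @param codes character vector of region codes, possibly with shorthand.
#' @return expanded character vector.
#' @export
expand_region_shorthand <- function(codes) {
  unlist(lapply(codes, function(cd) {
    if (cd == "CC") c("GCC", "BCC", "SCC")
    else if (grepl("\\.B$", cd)) paste0(sub("\\.B$", "", cd), c(".L", ".R"))
    else cd
  }), use.names = FALSE)
}

#' Rank accelerated regions by effect size
#'
#' Orders the significantly accelerated regions by descending partial
#' eta-squared (ties broken by region label order, so rankings are
#' deterministic) and returns the top `k`. Bilateral pairs remain separate
#' labels.
#'
#' @param results FDR-adjusted ANCOVA tibble with columns `region`,
#'   `label`, `partial_eta2`, `p_adj`, `mean_bag_patient`,
#'   `mean_bag_control` (an `accelerated` column is honoured, else
#'   computed with [flag_accelerated()]).
#' @param k number of regions to return (default 20); when fewer regions
#'   are significant, all are returned with a message.
#' @param alpha significance threshold for the flagging when needed.
#' @return tibble of the ranked regions with a `rank` column.
#' @export
rank_by_effect_size <- function(results, k = 20, alpha = 0.05) {
  if (!"accelerated" %in% names(results)) {
    results <- flag_accelerated(results, alpha = alpha)
  }
  sig <- results |>
    dplyr::filter(.data$accelerated) |>
    dplyr::arrange(dplyr::desc(.data$partial_eta2), .data$label)
  if (nrow(sig) < k) {
    rlang::inform(sprintf(
      "only %d significant region(s) available for k = %d; returning all",
      nrow(sig), k))
    k <- nrow(sig)
  }
  dplyr::mutate(head(sig, k), rank = dplyr::row_number())
}

#' Common and distinct region sets
#'
#' Exact label-set intersection and differences of two region lists (after
#' any shorthand expansion).
#'
#' @param list_a,list_b character vectors of region codes.
#' @param namespace optional character vector of valid codes (e.g.
#'   `aal_labels()$code`); unknown labels raise an error naming them.
#' @return list with `common`, `a_only`, `b_only` (sorted), and `counts`.
#' @export
common_and_distinct <- function(list_a, list_b, namespace = NULL) {
  if (!is.null(namespace)) {
    unknown <- setdiff(c(list_a, list_b), namespace)
    assert_that(length(unknown) == 0,
      paste0("unknown region label(s): ", paste(unknown, collapse = ", ")),
      class = "regionbag_validation_error")
  }
  common <- sort(intersect(list_a, list_b))
  a_only <- sort(setdiff(list_a, list_b))
  b_only <- sort(setdiff(list_b, list_a))
  list(common = common, a_only = a_only, b_only = b_only,
    counts = c(common = length(common), a_only = length(a_only),
      b_only = length(b_only)))
}
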
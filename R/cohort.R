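#' Cohort phenotype tables
#'
#' A cohort table is a tibble with one row per participant and the columns
#' `subject_id`, `age` (years), `sex` (`"male"`/`"female"`), `group`
#' (`"HC_train"`, `"HC_test"`, `"BD"`, `"MDD"`), and the clinical covariates
#' `mmse` (0-30), `education` (years), `ymrs`, `hamd21`, `hama`, and
#' `illness_duration` (years). Clinical fields may be `NA`; missingness is
#' kept explicit and handled per-analysis by listwise deletion. Row order is
#' the canonical subject ordering shared with every feature matrix derived
#' from the cohort.
#'
#' @name cohort
NULL

cohort_groups <- c("HC_train", "HC_test", "BD", "MDD")
cohort_sexes <- c("male", "female")

cohort_columns <- c(
  "subject_id", "age", "sex", "group", "mmse", "education",
  "ymrs", "hamd21", "hama", "illness_duration"
)

#' Validate a cohort table
#'
#' Checks the invariants every downstream stage relies on: unique subject
#' ids, ages within the configured range, and recognised sex and group
#' labels.
#'
#' @param cohort a data frame with at least `subject_id`, `age`, `sex`,
#'   `group`.
#' @param age_range permissible age interval in years.
#' @return the cohort as a tibble, invisibly augmented with any missing
#'   clinical columns (filled with `NA`).
#' @export
validate_cohort <- function(cohort, age_range = c(20, 84)) {
  assert_that(is.data.frame(cohort), "cohort must be a data frame")
  missing_cols <- setdiff(c("subject_id", "age", "sex", "group"), names(cohort))
  assert_that(
    length(missing_cols) == 0,
    paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
    class = "regionbag_config_error"
  )
  cohort <- tibble::as_tibble(cohort)
  dup <- cohort$subject_id[duplicated(cohort$subject_id)]
  assert_that(
    length(dup) == 0,
    paste0("duplicated subject_id: ", paste(unique(dup), collapse = ", ")),
    class = "regionbag_validation_error"
  )
  bad_group <- setdiff(unique(cohort$group), cohort_groups)
  assert_that(
    length(bad_group) == 0,
    paste0("unknown group label(s): ", paste(bad_group, collapse = ", ")),
    class = "regionbag_validation_error"
  )
  bad_sex <- setdiff(unique(cohort$sex), cohort_sexes)
  assert_that(
    length(bad_sex) == 0,
    paste0("unknown sex label(s): ", paste(bad_sex, collapse = ", ")),
    class = "regionbag_validation_error"
  )
  assert_that(
    all(is.finite(cohort$age)) &&
      all(cohort$age >= age_range[1] & cohort$age <= age_range[2]),
    sprintf("age outside [%g, %g] or non-finite", age_range[1], age_range[2]),
    class = "regionbag_validation_error"
  )
  for (col in setdiff(cohort_columns, names(cohort))) cohort[[col]] <- NA_real_
  cohort[, union(cohort_columns, names(cohort))]
}

#' Read a phenotype table from delimited text
#'
#' Reads a comma- or tab-delimited phenotype file, maps its columns onto the
#' cohort schema, and validates the result. Rows whose age cannot be parsed
#' or whose group label is unrecognised are dropped with a warning naming
#' them; structural problems (missing mandatory columns, duplicate ids) are
#' errors.
#'
#' @param path file path.
#' @param delim field delimiter; `","` (default) or `"\t"`.
#' @param col_map optional named character vector mapping cohort column
#'   names to the file's header names, e.g. `c(age = "Age_at_scan")`.
#' @param age_range permissible age interval in years.
#' @return a validated cohort tibble in file row order.
#' @export
read_cohort_table <- function(path, delim = ",", col_map = NULL,
                              age_range = c(20, 84)) {
  assert_that(file.exists(path), paste0("no such file: ", path),
    class = "regionbag_config_error")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE)
  if (!is.null(col_map)) {
    for (target in names(col_map)) {
      src <- col_map[[target]]
      assert_that(src %in% names(raw),
        paste0("mapped column not in file: ", src),
        class = "regionbag_config_error")
      names(raw)[names(raw) == src] <- target
    }
  }
  missing_cols <- setdiff(c("subject_id", "age", "sex", "group"), names(raw))
  assert_that(length(missing_cols) == 0,
    paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
    class = "regionbag_config_error")
  raw$age <- suppressWarnings(as.numeric(raw$age))
  bad <- !is.finite(raw$age) | !(raw$group %in% cohort_groups)
  if (any(bad)) {
    warn(paste0(
      "dropping ", sum(bad), " row(s) with unparseable age or unknown group: ",
      paste(raw$subject_id[bad], collapse = ", ")
    ))
    raw <- raw[!bad, , drop = FALSE]
  }
  out <- validate_cohort(raw, age_range = age_range)
  attr(out, "provenance") <- list(source = path, kind = "real")
  out
}

#' Write a cohort table to delimited text
#'
#' @param cohort a cohort tibble.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path, delim = ",") {
  readr::write_delim(cohort[, cohort_columns], path, delim = delim, na = "NA")
  invisible(path)
}
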
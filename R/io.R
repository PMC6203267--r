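# Cohort CSV round-tripping. The documented header is:
#   group, child_age, maternal_age, child_male, wessex, pgs, pas5, hads,
#   stress
# plus optional bookkeeping columns (respondent_role, scq, per-scale
# completion fractions). Missing values are written as empty fields.

cohort_required_cols <- function() {
  c("group", "child_age", "maternal_age", "child_male", "wessex",
    "pgs", "pas5", "hads", "stress")
}

cohort_col_types <- function() {
  readr::cols(
    group = readr::col_character(),
    child_age = readr::col_double(),
    maternal_age = readr::col_double(),
    child_male = readr::col_integer(),
    wessex = readr::col_integer(),
    pgs = readr::col_integer(),
    pas5 = readr::col_integer(),
    hads = readr::col_integer(),
    stress = readr::col_integer(),
    respondent_role = readr::col_character(),
    scq = readr::col_double(),
    .default = readr::col_double())
}

#' Read or write an analysis cohort as CSV
#'
#' `write_cohort()` then `read_cohort()` reproduces the table exactly,
#' including the empty-field encoding of missing scores.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  missing_cols <- setdiff(cohort_required_cols(), hdr)
  if (length(missing_cols))
    abort(sprintf("cohort file lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  extra <- setdiff(hdr, c(cohort_required_cols(), "respondent_role", "scq",
                          paste0(measure_names(), "_completion")))
  if (length(extra))
    warning(sprintf("ignoring unknown cohort column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  types <- cohort_col_types()
  types$cols <- types$cols[intersect(names(types$cols), hdr)]
  readr::read_csv(path, col_types = types, na = "")
}

#' @rdname read_cohort
#' @param cohort Cohort tibble (see [score_scales()]).
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_required_cols(), names(cohort))
  if (length(missing_cols))
    abort(sprintf("cohort lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Write a report table as CSV
#'
#' @param table A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, na = "")
  invisible(path)
}
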
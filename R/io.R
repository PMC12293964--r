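#' Read and write cohort tables as CSV
#'
#' The cohort layout is one row per subject: `subject_id`, `lesion_volume`
#' (mm^3), one named column per connectivity feature, and the outcome
#' column.
#'
#' @param path File path.
#' @param cohort Cohort data frame or a [simulate_cohort()] result.
#' @param outcome Outcome column expected on read (checked).
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, outcome = "nihss") {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(tab, c("lesion_volume", outcome))
  if (anyNA(tab[[outcome]])) {
    abort("The cohort outcome column contains missing values.")
  }
  tab
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Export the generating truth of a synthetic cohort as JSON-ready list
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A list with the generating coefficients, noise sd and design
#'   R-squared, suitable for `jsonlite::write_json()`.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  list(coefficients = as.list(tr$coefficients),
       noise_sd = tr$noise_sd,
       design_r2 = tr$design_r2)
}
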
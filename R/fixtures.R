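# Packaged fixtures: the two published study tables (transcribed values only,
# except explicitly marked external control-arm medians) plus a generated
# demonstration cohort standing in for the non-public patient-level data.

#' Load a packaged fixture as validated study records
#'
#' * `table1_comparative`: the 10 randomized phase-3 trials (15 scoring units:
#'   the Nordic trial contributes two arms, RTOG 9402 its printed molecular
#'   subgroups). Expected published scores travel as metadata, not as inputs.
#'   Rows whose ESMO grade depends on the control-arm median OS carry that
#'   median in a clearly marked, externally sourced column
#'   (`control_median_external = "yes"`).
#' * `table2_single_arm`: the 6 single-arm studies as 7 scoring units (the
#'   basket-trial cohorts scored separately), exactly one of which is expected
#'   not assessable.
#' * `mtbzpm_demo`: a synthetic 70-patient n-of-1 cohort generated with
#'   [default_cohort_config()] (the underlying observational-study patient
#'   data are not public).
#'
#' @param name `"table1_comparative"`, `"table2_single_arm"` or `"mtbzpm_demo"`.
#' @return List of [study_record()] objects; for the CSV fixtures the
#'   `"expected"` attribute is a data.frame of published scores keyed by
#'   `record_id` (`expected_*` columns; `"n/a:<reason>"` encodes a published
#'   not-assessable status).
#' @export
load_fixture <- function(name = c("table1_comparative", "table2_single_arm",
                                  "mtbzpm_demo")) {
  name <- match.arg(name)
  if (name == "mtbzpm_demo") {
    return(generate_cohort(default_cohort_config()))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "neuromcbs")
  records <- read_study_records(path, format = "csv")
  attr(records, "expected") <- attr(records, "extra")
  records
}

#' Split an expected-score annotation from the fixture metadata
#'
#' Fixture metadata encodes a published not-assessable status as
#' `"n/a:<reason>"` and a published score as the bare number.
#'
#' @param x a single expected-score string.
#' @return List with `status`, `reason` and `final`.
#' @export
parse_expected <- function(x) {
  if (grepl("^n/a:", x)) {
    list(status = "not_assessable", reason = sub("^n/a:", "", x), final = NA_integer_)
  } else {
    list(status = "scored", reason = NA_character_, final = as.integer(x))
  }
}
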
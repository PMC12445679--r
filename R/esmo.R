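# ESMO-MCBS v1.1 scoring: form router plus the Form 2a/2b/2c/3 engines.
# Comparative forms grade on the LOWER limit of the 95% CI of the hazard
# ratio; all forms apply highest-grade-fulfilled over the registry tables.

#' Route a study record to its ESMO-MCBS v1.1 form
#'
#' Single-arm and n-of-1 records go to Form 3; non-inferiority designs to Form
#' 2c; OS-primary trials to Form 2a; PFS-primary trials to Form 2b unless a
#' statistically significant OS benefit was demonstrated (upper 95% CI limit
#' of the OS hazard ratio below 1), in which case Form 2a is used per the Form
#' 2b instructions; other primary endpoints to Form 2c.
#'
#' @param record a [study_record()].
#' @return One of `"form2a"`, `"form2b"`, `"form2c"`, `"form3"`.
#' @export
select_form <- function(record) {
  validate_study_record(record)
  if (record$design %in% c("single_arm", "patient_n_of_1")) return("form3")
  if (record$design == "comparative_noninferiority") return("form2c")
  switch(record$primary_endpoint,
         OS = "form2a",
         PFS = {
           os_benefit <- !is.null(record$os) && !is.null(record$os$hr) &&
             record$os$hr$upper95 < 1
           if (os_benefit) "form2a" else "form2b"
         },
         "form2c")
}

endpoint_values <- function(ep) {
  vals <- list()
  if (!is.null(ep$hr)) vals$hr_lower95 <- ep$hr$lower95
  if (!is.na(ep$gain_months)) {
    vals$gain_months <- ep$gain_months
  } else if (!is.na(ep$landmark_gain_pct)) {
    # landmark-survival criteria are a fallback, used only when the median
    # gain is not reported (form precedence)
    vals$landmark_gain_pct <- ep$landmark_gain_pct
    vals$landmark_years <- as.double(ep$landmark_years)
  }
  vals
}

comparative_upgrade <- function(flags) {
  adj <- list()
  if (is_yes(flags$qol_improved)) {
    adj <- c(adj, list(adjustment("qol_upgrade", +1)))
  } else if (is_yes(flags$toxicity_reduced_vs_control)) {
    adj <- c(adj, list(adjustment("toxicity_upgrade", +1)))
  }
  adj
}

# Grade under both bands of a two-band form; returns list(grade, band_used,
# fired) or a character not-assessable reason.
banded_grade <- function(values, control_median, band_cut, table_le, table_gt) {
  if (!is.na(control_median)) {
    band <- if (control_median <= band_cut) "le_threshold" else "gt_threshold"
    tb <- if (band == "le_threshold") table_le else table_gt
    pg <- preliminary_grade(tb, values)
    return(list(grade = pg$grade, assessable = pg$assessable,
                band_used = band, fired = pg$fired))
  }
  # Control median unknown: evaluate both bands; a band-invariant grade needs
  # no external control-arm median, otherwise the record is not assessable
  # rather than guessed.
  lo <- preliminary_grade(table_le, values)
  hi <- preliminary_grade(table_gt, values)
  if (!lo$assessable || !hi$assessable) {
    return(list(grade = NA_integer_, assessable = FALSE,
                band_used = NA_character_, fired = c(lo$fired, hi$fired)))
  }
  if (lo$grade == hi$grade) {
    return(list(grade = lo$grade, assessable = TRUE,
                band_used = "band_invariant", fired = c(lo$fired, hi$fired)))
  }
  list(grade = NA_integer_, assessable = FALSE, band_used = "band_dependent",
       fired = c(lo$fired, hi$fired))
}

#' Score a comparative OS-primary trial (ESMO-MCBS v1.1 Form 2a)
#'
#' Preliminary grade (1-4) from the lower 95% CI limit of the OS hazard ratio
#' and the median OS gain, using the band determined by the control-arm median
#' OS (cut at 12 months). When the control median is unknown, both bands are
#' evaluated: an identical grade is reported as band-invariant; differing
#' grades make the record not assessable (`control_median_required`). A QoL or
#' toxicity upgrade adds 1 point for a maximum score of 5.
#'
#' @param record a comparative [study_record()] with OS data.
#' @param tables grade-table registry, see [mcbs_tables()].
#' @return An `mcbs_score`.
#' @export
score_form2a <- function(record, tables = mcbs_tables()) {
  validate_study_record(record)
  if (!is_yes(record$superiority_met)) {
    return(not_assessable("esmo_mcbs_v1_1", "form2a", record$record_id,
                          "no_statistical_significance"))
  }
  if (is.null(record$os)) {
    stop(sprintf("record '%s': Form 2a requires an OS endpoint", record$record_id),
         call. = FALSE)
  }
  values <- endpoint_values(record$os)
  bg <- banded_grade(values, record$os$control_median_months, 12,
                     tables$esmo_form2a_le12_v1_1, tables$esmo_form2a_gt12_v1_1)
  if (!bg$assessable) {
    reason <- if (identical(bg$band_used, "band_dependent"))
      "control_median_required" else "all_criteria_indeterminate"
    return(not_assessable("esmo_mcbs_v1_1", "form2a", record$record_id, reason,
                          audit = bg$fired))
  }
  new_score("esmo_mcbs_v1_1", "form2a", record$record_id,
            preliminary = bg$grade,
            adjustments = comparative_upgrade(record$flags),
            band_used = bg$band_used, audit = bg$fired)
}

#' Score a comparative PFS-primary trial (ESMO-MCBS v1.1 Form 2b)
#'
#' Preliminary grade (1-3) from the lower 95% CI limit of the PFS hazard
#' ratio and the median PFS gain (bands cut at a control-arm median PFS of 6
#' months, with the same band-invariance shortcut as Form 2a). Downgraded 1
#' point for the form's penalty conditions (early stopping / crossover,
#' carried as the `crossover_penalty` flag); upgraded 1 point for QoL
#' improvement or reduced toxicity. Maximum final score 4.
#'
#' @inheritParams score_form2a
#' @return An `mcbs_score`.
#' @export
score_form2b <- function(record, tables = mcbs_tables()) {
  validate_study_record(record)
  if (!is_yes(record$superiority_met)) {
    return(not_assessable("esmo_mcbs_v1_1", "form2b", record$record_id,
                          "no_statistical_significance"))
  }
  if (is.null(record$pfs)) {
    stop(sprintf("record '%s': Form 2b requires a PFS endpoint", record$record_id),
         call. = FALSE)
  }
  values <- endpoint_values(record$pfs)
  bg <- banded_grade(values, record$pfs$control_median_months, 6,
                     tables$esmo_form2b_le6_v1_1, tables$esmo_form2b_gt6_v1_1)
  if (!bg$assessable) {
    reason <- if (identical(bg$band_used, "band_dependent"))
      "control_median_required" else "all_criteria_indeterminate"
    return(not_assessable("esmo_mcbs_v1_1", "form2b", record$record_id, reason,
                          audit = bg$fired))
  }
  adj <- comparative_upgrade(record$flags)
  if (is_yes(record$flags$crossover_penalty)) {
    adj <- c(adj, list(adjustment("toxicity_downgrade", -1)))
  }
  new_score("esmo_mcbs_v1_1", "form2b", record$record_id,
            preliminary = bg$grade, adjustments = adj,
            band_used = bg$band_used, audit = bg$fired)
}

#' Score a non-inferiority or other-endpoint comparative trial (Form 2c)
#'
#' A non-inferiority trial is scoreable only when statistical non-inferiority
#' was met AND there is positive evidence of reduced toxicity or improved
#' quality of life; with that evidence the form awards its maximum of 4. When
#' the toxicity/QoL evidence is unreported the record is not assessable
#' (`insufficient_toxicity_data`); explicit negative evidence scores 0 (no
#' demonstrable benefit). Superiority trials with a primary endpoint other
#' than OS/PFS receive a conservative preliminary 2, upgradeable by 1 for
#' QoL/toxicity credit.
#'
#' @inheritParams score_form2a
#' @return An `mcbs_score`.
#' @export
score_form2c <- function(record, tables = mcbs_tables()) {
  validate_study_record(record)
  fl <- record$flags
  benefit_evidence <- is_yes(fl$toxicity_reduced_vs_control) || is_yes(fl$qol_improved)
  evidence_unknown <- fl$toxicity_reduced_vs_control == "unknown" &&
    fl$qol_improved == "unknown"
  if (record$design == "comparative_noninferiority") {
    if (!is_yes(record$noninferiority_met)) {
      return(not_assessable("esmo_mcbs_v1_1", "form2c", record$record_id,
                            "no_statistical_significance"))
    }
    if (benefit_evidence) {
      return(new_score("esmo_mcbs_v1_1", "form2c", record$record_id,
                       preliminary = 4L,
                       notes = "non-inferior with reduced toxicity and/or improved QoL"))
    }
    if (evidence_unknown) {
      return(not_assessable("esmo_mcbs_v1_1", "form2c", record$record_id,
                            "insufficient_toxicity_data"))
    }
    return(new_score("esmo_mcbs_v1_1", "form2c", record$record_id,
                     preliminary = 0L,
                     notes = "non-inferior but no toxicity/QoL advantage demonstrated"))
  }
  if (!is_yes(record$superiority_met)) {
    return(not_assessable("esmo_mcbs_v1_1", "form2c", record$record_id,
                          "no_statistical_significance"))
  }
  new_score("esmo_mcbs_v1_1", "form2c", record$record_id, preliminary = 2L,
            adjustments = comparative_upgrade(record$flags),
            notes = "superiority on a non-OS/PFS primary endpoint")
}

#' Score a single-arm study (ESMO-MCBS v1.1 Form 3)
#'
#' Preliminary grade (1-3) from median PFS, ORR and duration of response via
#' the transcribed Form 3 table; downgraded 1 point when >= 30% of patients
#' had grade 3-4 toxicities, upgraded 1 point for objective QoL improvement;
#' maximum final score 4. When the only potentially satisfiable criteria
#' require a missing DoR the record is not assessable
#' (`duration_of_response_missing`).
#'
#' @param record a single-arm or n-of-1 [study_record()].
#' @inheritParams score_form2a
#' @param audit keep the per-criterion audit trail (disable in bulk scoring).
#' @return An `mcbs_score`.
#' @export
score_form3 <- function(record, tables = mcbs_tables(), audit = TRUE) {
  validate_study_record(record)
  if (!record$design %in% c("single_arm", "patient_n_of_1")) {
    stop(sprintf("record '%s': Form 3 applies to single-arm designs only",
                 record$record_id), call. = FALSE)
  }
  r <- record$response
  values <- compact(list(
    pfs_months = if (is.na(record$single_arm_pfs_months)) NULL else record$single_arm_pfs_months,
    orr_pct = if (is.null(r) || is.na(r$orr_pct)) NULL else r$orr_pct,
    dor_months = if (is.null(r) || is.na(r$dor_months)) NULL else r$dor_months))
  pg <- preliminary_grade(tables$esmo_form3_v1_1, values, audit = audit)
  single_arm_result("esmo_mcbs_v1_1", "form3", record, pg,
                    dur_metrics = "dor_months")
}

# Shared Form 3 / Neuro-MCBS result assembly: not-assessable states, toxicity
# downgrade, QoL upgrade.
single_arm_result <- function(scale_id, form_id, record, pg,
                              dur_metrics, extra_upgrade_phase4 = FALSE,
                              proxies = character(0)) {
  notes <- if (length(proxies))
    sprintf("proxy substitution: %s", paste(proxies, collapse = "; ")) else character(0)
  if (!pg$assessable) {
    return(not_assessable(scale_id, form_id, record$record_id,
                          "all_criteria_indeterminate",
                          audit = pg$fired %||% list(), notes = notes))
  }
  # a criterion whose head interval held was blocked solely by an unreported
  # duration: the grade could have been higher, so the record is not scoreable
  # at 0 (criteria missing their head metric outright do not trigger this)
  duration_blocked <- any(vapply(pg$indeterminate_sets, function(mm)
    length(mm) > 0 && all(mm %in% dur_metrics), logical(1)))
  if (pg$grade == 0 && duration_blocked) {
    return(not_assessable(scale_id, form_id, record$record_id,
                          "duration_of_response_missing",
                          audit = pg$fired %||% list(), notes = notes))
  }
  adj <- list()
  if (is_yes(record$flags$toxicity_ge30pct_grade34)) {
    adj <- c(adj, list(adjustment("toxicity_downgrade", -1)))
  }
  if (is_yes(record$flags$qol_improved)) {
    adj <- c(adj, list(adjustment("qol_upgrade", +1)))
  } else if (extra_upgrade_phase4 && is_yes(record$flags$phase4_confirmation)) {
    adj <- c(adj, list(adjustment("phase4_upgrade", +1)))
  }
  new_score(scale_id, form_id, record$record_id, preliminary = pg$grade,
            adjustments = adj, audit = pg$fired %||% list(), notes = notes)
}

#' Score a record with the ESMO-MCBS v1.1 (automatic form selection)
#'
#' @param record a [study_record()].
#' @param tables grade-table registry, see [mcbs_tables()].
#' @return An `mcbs_score` from the routed form engine.
#' @export
score_esmo <- function(record, tables = mcbs_tables()) {
  switch(select_form(record),
         form2a = score_form2a(record, tables),
         form2b = score_form2b(record, tables),
         form2c = score_form2c(record, tables),
         form3 = score_form3(record, tables))
}
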
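# Neuro-MCBS: single-arm benefit grading on PFS, ORR, DCR and duration of
# clinical benefit, with toxicity downgrade and QoL / phase-4 upgrade, summed
# and capped at 4.

#' Proxy policy for Neuro-MCBS scoring
#'
#' Published single-arm tables often report ORR but not DCR, and duration of
#' response (DoR) rather than duration of clinical benefit (DoCB). Because
#' responders (CR+PR+MR) are a subset of disease control (CR+PR+MR+SD), ORR is
#' a certified lower bound of DCR and substitution can only under-grade, never
#' over-grade; likewise DoR is accepted for DoCB. Every substitution is
#' recorded in the result's audit notes.
#'
#' @param allow_orr_as_dcr_floor substitute ORR when DCR is missing.
#' @param allow_dor_as_docb substitute DoR when DoCB is missing.
#' @param dcr_band_mode `"as_printed"` keeps the literal DCR band upper bounds
#'   (a DCR above a band ceiling with no higher-grade path triggers a warning);
#'   `"monotone"` drops the DCR upper bounds so the score is non-decreasing in
#'   DCR.
#' @return An object of class `proxy_policy`.
#' @export
proxy_policy <- function(allow_orr_as_dcr_floor = TRUE,
                         allow_dor_as_docb = TRUE,
                         dcr_band_mode = c("as_printed", "monotone")) {
  structure(list(allow_orr_as_dcr_floor = isTRUE(allow_orr_as_dcr_floor),
                 allow_dor_as_docb = isTRUE(allow_dor_as_docb),
                 dcr_band_mode = match.arg(dcr_band_mode)),
            class = "proxy_policy")
}

neuro_values <- function(record, policy) {
  r <- record$response
  values <- compact(list(
    pfs_months = if (is.na(record$single_arm_pfs_months)) NULL else record$single_arm_pfs_months,
    orr_pct = if (is.null(r) || is.na(r$orr_pct)) NULL else r$orr_pct,
    dcr_pct = if (is.null(r) || is.na(r$dcr_pct)) NULL else r$dcr_pct,
    docb_months = if (is.null(r) || is.na(r$docb_months)) NULL else r$docb_months))
  proxies <- character(0); proxied <- character(0)
  if (is.null(values$dcr_pct) && policy$allow_orr_as_dcr_floor &&
      !is.null(values$orr_pct)) {
    values$dcr_pct <- values$orr_pct
    proxied <- c(proxied, "dcr_pct")
    proxies <- c(proxies, "ORR used as lower bound for missing DCR")
  }
  if (is.null(values$docb_months) && policy$allow_dor_as_docb &&
      !is.null(r) && !is.na(r$dor_months)) {
    values$docb_months <- r$dor_months
    proxied <- c(proxied, "docb_months")
    proxies <- c(proxies, sprintf("DoR (%s) used for missing DoCB", r$dor_statistic))
  }
  list(values = values, proxied = proxied, proxies = proxies)
}

#' Score a single-arm study or patient with the Neuro-MCBS
#'
#' Step 1 awards the highest grade (1-3) whose criterion row is satisfied
#' (PFS, ORR, or DCR with a duration-of-clinical-benefit companion); Step 2
#' downgrades 1 level for >= 30% grade 3-4 toxicities impacting daily
#' well-being and upgrades 1 level for objective QoL improvement or
#' confirmatory phase-4 experience (a single +1 even if both hold); Step 3
#' sums, with a maximum final score of 4 and a floor of 0 ("no demonstrable
#' benefit", distinct from not assessable).
#'
#' @param record a single-arm or n-of-1 [study_record()].
#' @param policy a [proxy_policy()].
#' @param tables grade-table registry, see [mcbs_tables()].
#' @param audit keep the per-criterion audit trail (disable in bulk scoring).
#' @return An `mcbs_score` with `scale_id = "neuro_mcbs_v1"`.
#' @export
score_neuro_mcbs <- function(record, policy = proxy_policy(),
                             tables = mcbs_tables(), audit = TRUE) {
  validate_study_record(record)
  if (!record$design %in% c("single_arm", "patient_n_of_1")) {
    stop(sprintf("record '%s': the Neuro-MCBS applies to single-arm designs only",
                 record$record_id), call. = FALSE)
  }
  table <- tables$neuro_mcbs_v1
  if (policy$dcr_band_mode == "monotone") table <- monotonize_table(table)
  nv <- neuro_values(record, policy)
  pg <- preliminary_grade(table, nv$values, proxied = nv$proxied, audit = audit)
  if (audit && policy$dcr_band_mode == "as_printed" && isTRUE(pg$assessable) &&
      !is.null(nv$values$dcr_pct) && nv$values$dcr_pct >= 60 &&
      (is.null(nv$values$orr_pct) || nv$values$orr_pct < 60) && pg$grade < 3) {
    warning(sprintf(paste("record '%s': DCR %.0f%% exceeds the printed band upper",
                          "bounds without a higher-grade path; consider",
                          "dcr_band_mode = 'monotone'"),
                    record$record_id, nv$values$dcr_pct), call. = FALSE)
  }
  res <- single_arm_result("neuro_mcbs_v1", "neuro_mcbs", record, pg,
                           dur_metrics = "docb_months",
                           extra_upgrade_phase4 = TRUE, proxies = nv$proxies)
  res$notes <- c(res$notes, sprintf("policy: dcr_band_mode=%s", policy$dcr_band_mode))
  res
}

#' Score an individual patient as an n-of-1 single arm
#'
#' A patient's best radiographic response is converted to degenerate rates
#' (ORR 100 if the best response is CR/PR/MR else 0; DCR 100 if CR/PR/MR/SD
#' else 0) and the Neuro-MCBS is applied to the patient's own PFS and duration
#' of clinical benefit.
#'
#' @param patient a [study_record()] with `design = "patient_n_of_1"`, a best
#'   response category and/or PFS in months.
#' @inheritParams score_neuro_mcbs
#' @return An `mcbs_score`.
#' @export
score_patient <- function(patient, policy = proxy_policy(),
                          tables = mcbs_tables(), audit = TRUE) {
  stopifnot(inherits(patient, "study_record"))
  if (patient$design != "patient_n_of_1") {
    stop(sprintf("record '%s': score_patient() requires design patient_n_of_1",
                 patient$record_id), call. = FALSE)
  }
  if (is.na(patient$best_response) && is.na(patient$single_arm_pfs_months)) {
    return(not_assessable("neuro_mcbs_v1", "neuro_mcbs", patient$record_id,
                          "all_criteria_indeterminate",
                          notes = "neither best response nor PFS recorded"))
  }
  if (!is.na(patient$best_response)) {
    orr <- if (patient$best_response %in% c("CR", "PR", "MR")) 100 else 0
    dcr <- if (patient$best_response %in% c("CR", "PR", "MR", "SD")) 100 else 0
    r <- patient$response
    patient$response <- response_summary(
      orr_pct = orr, dcr_pct = dcr,
      dor_months = if (is.null(r)) NA_real_ else r$dor_months,
      dor_statistic = if (is.null(r)) "unspecified" else r$dor_statistic,
      docb_months = if (is.null(r)) NA_real_ else r$docb_months,
      response_criteria = if (is.null(r)) NA_character_ else r$response_criteria)
  }
  score_neuro_mcbs(patient, policy = policy, tables = tables, audit = audit)
}

#' Score a list of records
#'
#' @param records list of [study_record()] objects.
#' @param scale `"neuro"` (Neuro-MCBS; n-of-1 records via [score_patient()]),
#'   `"esmo"` (form-routed ESMO-MCBS v1.1) or `"both"`.
#' @param policy a [proxy_policy()] (Neuro-MCBS only).
#' @param tables grade-table registry.
#' @param audit keep per-criterion audit trails.
#' @return List of `mcbs_score` objects (for `"both"`, a list with elements
#'   `neuro` and `esmo`).
#' @export
score_records <- function(records, scale = c("neuro", "esmo", "both"),
                          policy = proxy_policy(), tables = mcbs_tables(),
                          audit = TRUE) {
  scale <- match.arg(scale)
  run_neuro <- function() lapply(records, function(rec) {
    if (rec$design == "patient_n_of_1") {
      score_patient(rec, policy, tables, audit = audit)
    } else {
      score_neuro_mcbs(rec, policy, tables, audit = audit)
    }
  })
  run_esmo <- function() lapply(records, score_esmo, tables = tables)
  switch(scale,
         neuro = run_neuro(),
         esmo = run_esmo(),
         both = list(neuro = run_neuro(), esmo = run_esmo()))
}
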
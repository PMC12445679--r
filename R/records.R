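DESIGNS <- c("comparative_superiority", "comparative_noninferiority",
             "single_arm", "patient_n_of_1")
ENDPOINTS <- c("OS", "PFS", "ORR", "other", "safety")
RESPONSES <- c("CR", "PR", "MR", "SD", "PD")

#' Hazard-ratio estimate with 95% confidence limits
#'
#' The ESMO-MCBS forms grade comparative trials on the lower limit of the 95%
#' confidence interval of the hazard ratio (LL95%CI), while the ASCO framework
#' uses the point estimate; this container carries all three.
#'
#' @param point,lower95,upper95 positive reals with `lower95 <= point <= upper95`.
#' @return An object of class `hr_estimate`.
#' @export
hr_estimate <- function(point, lower95, upper95) {
  stopifnot(is.numeric(point), is.numeric(lower95), is.numeric(upper95))
  if (any(c(point, lower95, upper95) <= 0)) {
    stop("hazard ratio and its confidence limits must be strictly positive",
         call. = FALSE)
  }
  if (!(lower95 <= point && point <= upper95)) {
    stop("hazard ratio CI must satisfy lower95 <= point <= upper95", call. = FALSE)
  }
  structure(list(point = point, lower95 = lower95, upper95 = upper95),
            class = "hr_estimate")
}

#' Parse a printed hazard-ratio cell such as "0.63 (0.53-0.75)"
#'
#' Accepts period or middle-dot decimals and hyphen or en-dash range
#' separators, as found in published trial tables. The explicit missing token
#' `"(-)"` or an empty cell yields `NULL`.
#'
#' @param text a single character cell.
#' @return An [hr_estimate()] or `NULL` when the cell is the missing token.
#' @examples
#' parse_hr_ci("0.63 (0.53-0.75)")
#' parse_hr_ci("0·63 (0·53–0·75)")  # middle dots, en dash
#' @export
parse_hr_ci <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  x <- trimws(as.character(text))
  if (!nzchar(x) || x == "(-)") return(NULL)
  x <- gsub("·", ".", x)                 # middle dot decimals
  x <- gsub("[–—−]", "-", x)   # en/em dash, unicode minus
  m <- regmatches(x, regexec(
    "^\\s*([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]*\\.?[0-9]+)\\s*-\\s*([0-9]*\\.?[0-9]+)\\s*\\)\\s*$",
    x))[[1]]
  if (length(m) != 4) {
    stop(sprintf("cannot parse hazard-ratio cell '%s'", text), call. = FALSE)
  }
  v <- as.numeric(m[2:4])
  hr_estimate(point = v[1], lower95 = v[2], upper95 = v[3])
}

#' Normalize a duration to months
#'
#' Trial tables mix units (e.g. survival gains reported in years for low-grade
#' glioma trials); all engine arithmetic is in months.
#'
#' @param value non-negative duration.
#' @param unit `"months"` or `"years"`.
#' @return Duration in months.
#' @examples
#' normalize_duration(5.5, "years")  # 66
#' @export
normalize_duration <- function(value, unit = c("months", "years")) {
  unit <- match.arg(unit)
  if (is.na(value)) return(NA_real_)
  if (value < 0) stop("durations must be non-negative", call. = FALSE)
  if (unit == "years") value * 12 else value
}

#' Survival endpoint summary (OS or PFS) of a comparative trial
#'
#' @param endpoint_kind `"OS"` or `"PFS"`.
#' @param gain_months median gain over control in months (may be negative for
#'   a detriment, as printed in some trial tables); `NA` if not reported.
#' @param control_median_months control-arm median in months (band selector for
#'   the ESMO forms); `NA` if not reported.
#' @param hr an [hr_estimate()] or `NULL`.
#' @param landmark_gain_pct absolute gain in landmark (2- or 3-year) survival,
#'   percentage points; used only when `gain_months` is missing.
#' @param landmark_years the landmark horizon in years.
#' @return An object of class `survival_endpoint`.
#' @export
survival_endpoint <- function(endpoint_kind = c("OS", "PFS"),
                              gain_months = NA_real_,
                              control_median_months = NA_real_,
                              hr = NULL,
                              landmark_gain_pct = NA_real_,
                              landmark_years = NA_integer_) {
  endpoint_kind <- match.arg(endpoint_kind)
  if (!is.null(hr) && !inherits(hr, "hr_estimate")) {
    stop("'hr' must be an hr_estimate or NULL", call. = FALSE)
  }
  if (!is.na(landmark_gain_pct) && is.na(landmark_years)) {
    stop("landmark_gain_pct requires landmark_years", call. = FALSE)
  }
  if (!is.na(control_median_months) && control_median_months <= 0) {
    stop("control_median_months must be positive", call. = FALSE)
  }
  structure(list(endpoint_kind = endpoint_kind,
                 gain_months = as.double(gain_months),
                 control_median_months = as.double(control_median_months),
                 hr = hr,
                 landmark_gain_pct = as.double(landmark_gain_pct),
                 landmark_years = as.integer(landmark_years)),
            class = "survival_endpoint")
}

#' Tumor response summary of a single-arm study or patient
#'
#' Rates are on the 0-100 scale as printed. ORR counts CR + PR + MR (minor
#' response, recognized for non-enhancing tumors under RANO 2.0); DCR adds SD.
#' A "not reached" duration is stored as `Inf`: it satisfies any finite
#' lower-bound criterion.
#'
#' @param orr_pct,dcr_pct response / disease-control rates in \[0, 100\].
#' @param dor_months duration of response, months; `Inf` for "not reached".
#' @param dor_statistic `"mean"`, `"median"` or `"unspecified"`.
#' @param docb_months duration of clinical benefit, months; `Inf` allowed.
#' @param response_criteria free text (e.g. `"RANO"`, `"volumetric MRI"`).
#' @return An object of class `response_summary`.
#' @export
response_summary <- function(orr_pct = NA_real_, dcr_pct = NA_real_,
                             dor_months = NA_real_,
                             dor_statistic = c("unspecified", "mean", "median"),
                             docb_months = NA_real_,
                             response_criteria = NA_character_) {
  dor_statistic <- match.arg(dor_statistic)
  for (v in list(orr = orr_pct, dcr = dcr_pct)) {
    if (!is.na(v) && (v < 0 || v > 100)) {
      stop("response rates must lie in [0, 100]", call. = FALSE)
    }
  }
  if (!is.na(orr_pct) && !is.na(dcr_pct) && dcr_pct < orr_pct) {
    stop("dcr_pct must be >= orr_pct (DCR is ORR plus stable disease)",
         call. = FALSE)
  }
  for (v in list(dor = dor_months, docb = docb_months)) {
    if (!is.na(v) && v < 0) stop("durations must be non-negative", call. = FALSE)
  }
  structure(list(orr_pct = as.double(orr_pct), dcr_pct = as.double(dcr_pct),
                 dor_months = as.double(dor_months), dor_statistic = dor_statistic,
                 docb_months = as.double(docb_months),
                 response_criteria = as.character(response_criteria)),
            class = "response_summary")
}

#' Toxicity / quality-of-life adjustment flags
#'
#' Ternary (`yes`/`no`/`unknown`) rather than logical, because published tables
#' distinguish "no" from "not reported": an unknown flag blocks an upgrade but
#' never triggers a downgrade.
#'
#' @param toxicity_ge30pct_grade34 >= 30% grade 3-4 toxicities impacting daily
#'   well-being (excluding myelosuppression and asymptomatic laboratory
#'   abnormalities) - the downgrade trigger.
#' @param toxicity_reduced_vs_control significant toxicity reduction versus the
#'   control arm (comparative upgrade credit).
#' @param qol_assessed,qol_improved quality of life evaluated as a secondary
#'   outcome / objectively improved.
#' @param phase4_confirmation confirmatory, adequately sized phase-4 experience.
#' @param crossover_penalty form 2b penalty conditions (early stopping or
#'   crossover confounding the PFS comparison).
#' @return An object of class `adjustment_flags`.
#' @export
adjustment_flags <- function(toxicity_ge30pct_grade34 = "unknown",
                             toxicity_reduced_vs_control = "unknown",
                             qol_assessed = "unknown",
                             qol_improved = "unknown",
                             phase4_confirmation = "unknown",
                             crossover_penalty = "unknown") {
  out <- list(
    toxicity_ge30pct_grade34 = as_ternary(toxicity_ge30pct_grade34, "toxicity_ge30pct_grade34"),
    toxicity_reduced_vs_control = as_ternary(toxicity_reduced_vs_control, "toxicity_reduced_vs_control"),
    qol_assessed = as_ternary(qol_assessed, "qol_assessed"),
    qol_improved = as_ternary(qol_improved, "qol_improved"),
    phase4_confirmation = as_ternary(phase4_confirmation, "phase4_confirmation"),
    crossover_penalty = as_ternary(crossover_penalty, "crossover_penalty"))
  if (is_yes(out$qol_improved) && out$qol_assessed == "no") {
    stop("qol_improved = yes requires qol_assessed = yes", call. = FALSE)
  }
  if (is_yes(out$qol_improved)) out$qol_assessed <- "yes"
  structure(out, class = "adjustment_flags")
}

#' Structured study-outcome record
#'
#' One scoring unit: a comparative trial (or trial arm/subgroup), a single-arm
#' study (or a cohort of a basket trial), or an individual patient treated as
#' an n-of-1 single arm.
#'
#' @param record_id caller-supplied stable identifier (audit trails key on it).
#' @param design one of `comparative_superiority`, `comparative_noninferiority`,
#'   `single_arm`, `patient_n_of_1`.
#' @param primary_endpoint one of `OS`, `PFS`, `ORR`, `other`, `safety`.
#' @param n_subjects arm/study size, or `NA`.
#' @param superiority_met,noninferiority_met ternary: did the primary
#'   comparison reach statistical significance / non-inferiority.
#' @param os,pfs [survival_endpoint()] objects or `NULL` (comparative designs).
#' @param single_arm_pfs_months median PFS of a single-arm unit, months.
#' @param response a [response_summary()] or `NULL`.
#' @param best_response best radiographic response category of an n-of-1
#'   patient (`CR`/`PR`/`MR`/`SD`/`PD`) or `NA`.
#' @param flags an [adjustment_flags()].
#' @param subgroup_label,entity,therapy_class,note free-text annotations.
#' @return An object of class `study_record`.
#' @export
study_record <- function(record_id,
                         design,
                         primary_endpoint = "other",
                         n_subjects = NA_integer_,
                         superiority_met = "unknown",
                         noninferiority_met = "unknown",
                         os = NULL, pfs = NULL,
                         single_arm_pfs_months = NA_real_,
                         response = NULL,
                         best_response = NA_character_,
                         flags = adjustment_flags(),
                         subgroup_label = NA_character_,
                         entity = NA_character_,
                         therapy_class = NA_character_,
                         note = NA_character_) {
  design <- match.arg(design, DESIGNS)
  primary_endpoint <- match.arg(primary_endpoint, ENDPOINTS)
  stopifnot(is.character(record_id), length(record_id) == 1, nzchar(record_id))
  if (!is.null(os)) stopifnot(inherits(os, "survival_endpoint"))
  if (!is.null(pfs)) stopifnot(inherits(pfs, "survival_endpoint"))
  if (!is.null(response)) stopifnot(inherits(response, "response_summary"))
  stopifnot(inherits(flags, "adjustment_flags"))
  if (!is.na(best_response)) best_response <- match.arg(best_response, RESPONSES)
  rec <- structure(list(
    record_id = record_id, design = design,
    primary_endpoint = primary_endpoint,
    n_subjects = as.integer(n_subjects),
    superiority_met = as_ternary(superiority_met, "superiority_met"),
    noninferiority_met = as_ternary(noninferiority_met, "noninferiority_met"),
    os = os, pfs = pfs,
    single_arm_pfs_months = as.double(single_arm_pfs_months),
    response = response, best_response = best_response,
    flags = flags,
    subgroup_label = as.character(subgroup_label),
    entity = as.character(entity),
    therapy_class = as.character(therapy_class),
    note = as.character(note)),
    class = "study_record")
  validate_study_record(rec)
  rec
}

#' Validate a study record against the type invariants
#'
#' @param rec a [study_record()].
#' @return `rec`, invisibly; signals an error describing the violated invariant.
#' @export
validate_study_record <- function(rec) {
  stopifnot(inherits(rec, "study_record"))
  comparative <- rec$design %in% c("comparative_superiority",
                                   "comparative_noninferiority")
  has_effect <- function(ep) {
    !is.null(ep) && (!is.null(ep$hr) || !is.na(ep$gain_months) ||
                       !is.na(ep$landmark_gain_pct))
  }
  if (comparative && !has_effect(rec$os) && !has_effect(rec$pfs)) {
    stop(sprintf("record '%s': comparative design requires OS or PFS data (hr or gain)",
                 rec$record_id), call. = FALSE)
  }
  if (!comparative) {
    if ((!is.null(rec$os) && !is.null(rec$os$hr)) ||
        (!is.null(rec$pfs) && !is.null(rec$pfs$hr))) {
      stop(sprintf("record '%s': single-arm designs cannot carry hazard ratios",
                   rec$record_id), call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record %s> %s, primary endpoint %s\n",
              x$record_id, x$design, x$primary_endpoint))
  if (!is.na(x$entity)) cat("  entity:", x$entity, "\n")
  if (!is.null(x$os) && !is.null(x$os$hr)) {
    cat(sprintf("  OS: gain %s mo, HR %.2f (%.2f-%.2f)\n",
                format_cell_number(x$os$gain_months), x$os$hr$point,
                x$os$hr$lower95, x$os$hr$upper95))
  }
  if (!is.na(x$single_arm_pfs_months)) {
    cat("  mPFS:", format_cell_number(x$single_arm_pfs_months), "months\n")
  }
  if (!is.null(x$response)) {
    cat(sprintf("  ORR %s%%, DCR %s%%, DoR %s mo, DoCB %s mo\n",
                format_cell_number(x$response$orr_pct),
                format_cell_number(x$response$dcr_pct),
                format_cell_number(x$response$dor_months),
                format_cell_number(x$response$docb_months)))
  }
  invisible(x)
}
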
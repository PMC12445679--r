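# ASCO value framework v2: net health benefit (NHB) = clinical-benefit points
# + toxicity points + (advanced setting only) bonus points, capped at 130
# (advanced) or 100 (adjuvant). The point schedule ships as a versioned
# parameter file; the framework applies to randomized superiority trials only.

.asco_cache <- new.env(parent = emptyenv())

#' Load the ASCO-NHB v2 point schedule
#'
#' @param path optional alternative parameter file; defaults to the packaged
#'   `asco_nhb_v2.yaml`.
#' @return Named list of point parameters.
#' @export
asco_params <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.asco_cache$params)) return(.asco_cache$params)
  if (is.null(path)) {
    path <- system.file("extdata", "asco_nhb_v2.yaml", package = "neuromcbs")
  }
  params <- yaml::read_yaml(path)
  if (default) .asco_cache$params <- params
  params
}

#' Inputs for ASCO-NHB v2 scoring
#'
#' @param clinical_benefit_basis `"os_hr"`, `"pfs_hr"` or `"rr"`: which trial
#'   outcome drives the clinical-benefit points.
#' @param hr an [hr_estimate()]; required for the hazard-ratio bases (the
#'   POINT estimate is used, unlike ESMO grading).
#' @param rr_diff_pct absolute response-rate difference in percentage points;
#'   required for the `"rr"` basis.
#' @param toxicity_profile `NULL` (unreported: the toxicity component is
#'   excluded and the result flagged partial) or a list with `treatment_pct`
#'   and `control_pct`, the per-arm grade 3-4 toxicity rates.
#' @param bonus named list of logical bonus flags (`tail_of_curve`,
#'   `palliation`, `qol_improved`, `treatment_free_interval`); advanced
#'   setting only.
#' @return An object of class `asco_inputs`.
#' @export
asco_inputs <- function(clinical_benefit_basis = c("os_hr", "pfs_hr", "rr"),
                        hr = NULL, rr_diff_pct = NA_real_,
                        toxicity_profile = NULL, bonus = list()) {
  basis <- match.arg(clinical_benefit_basis)
  if (basis %in% c("os_hr", "pfs_hr")) {
    if (is.null(hr)) stop("hazard-ratio basis requires 'hr'", call. = FALSE)
    stopifnot(inherits(hr, "hr_estimate"))
  } else if (is.na(rr_diff_pct)) {
    stop("response-rate basis requires 'rr_diff_pct'", call. = FALSE)
  }
  if (!is.null(toxicity_profile)) {
    stopifnot(is.list(toxicity_profile),
              all(c("treatment_pct", "control_pct") %in% names(toxicity_profile)))
  }
  structure(list(clinical_benefit_basis = basis, hr = hr,
                 rr_diff_pct = as.double(rr_diff_pct),
                 toxicity_profile = toxicity_profile, bonus = bonus),
            class = "asco_inputs")
}

#' Score a randomized trial with the ASCO-NHB v2 framework
#'
#' @param record a comparative superiority [study_record()] (the framework
#'   does not support non-inferiority designs; such records return
#'   `not_assessable(noninferiority_design_unsupported)`).
#' @param inputs an [asco_inputs()].
#' @param setting `"advanced"` (max 130, bonus points allowed) or
#'   `"adjuvant"` (max 100, outcome and toxicity only).
#' @param params point schedule, see [asco_params()].
#' @return An `mcbs_score` whose `final` is the NHB; `audit` holds the exact
#'   point decomposition (components sum to the final score; a binding cap is
#'   itself a component).
#' @export
score_asco <- function(record, inputs, setting = c("advanced", "adjuvant"),
                       params = asco_params()) {
  setting <- match.arg(setting)
  form_id <- paste0("asco_", setting)
  validate_study_record(record)
  stopifnot(inherits(inputs, "asco_inputs"))
  if (record$design == "comparative_noninferiority") {
    return(not_assessable("asco_nhb_v2", form_id, record$record_id,
                          "noninferiority_design_unsupported"))
  }
  if (!record$design == "comparative_superiority") {
    stop(sprintf("record '%s': the ASCO framework applies to randomized comparative trials only",
                 record$record_id), call. = FALSE)
  }
  if (!is_yes(record$superiority_met)) {
    return(not_assessable("asco_nhb_v2", form_id, record$record_id,
                          "no_statistical_significance"))
  }
  components <- list(); notes <- character(0)
  cb_max <- params$clinical_benefit$max_points
  cb <- if (inputs$clinical_benefit_basis == "rr") {
    inputs$rr_diff_pct * params$clinical_benefit$multiplier$rr / 100
  } else {
    (1 - inputs$hr$point) *
      params$clinical_benefit$multiplier[[inputs$clinical_benefit_basis]]
  }
  cb <- min(max(cb, 0), cb_max)
  components$clinical_benefit <- cb
  tp <- inputs$toxicity_profile
  if (is.null(tp)) {
    notes <- c(notes, "toxicity data unreported: component excluded, score partial")
  } else {
    denom <- max(tp$control_pct, tp$treatment_pct)
    frac <- if (denom > 0) (tp$control_pct - tp$treatment_pct) / denom else 0
    tmax <- params$toxicity$max_points
    components$toxicity <- min(max(tmax * frac, -tmax), tmax)
  }
  if (setting == "advanced") {
    for (b in names(params$bonus)) {
      if (isTRUE(inputs$bonus[[b]])) components[[paste0("bonus_", b)]] <- params$bonus[[b]]
    }
  }
  nhb <- sum(unlist(components))
  cap <- params$caps[[setting]]
  if (nhb > cap) {
    components$cap_adjustment <- cap - nhb
    nhb <- cap
  }
  structure(list(scale_id = "asco_nhb_v2", form_id = form_id,
                 record_id = record$record_id, status = "scored",
                 not_assessable_reason = NA_character_,
                 preliminary = components$clinical_benefit,
                 adjustments = lapply(names(components)[-1], function(k)
                   adjustment(k, components[[k]])),
                 final = nhb, max_score = cap, band_used = NA_character_,
                 audit = components, notes = notes),
            class = "mcbs_score")
}
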
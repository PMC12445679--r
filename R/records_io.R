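# Flat CSV schema: one row per scoring unit. Durations are normalized to
# months at load time (os_gain/pfs_gain carry an optional *_unit column so a
# file can hold values exactly as printed, e.g. gains in years); hazard ratios
# are printed cells like "0.63 (0.53-0.75)"; missing is an empty cell or "(-)";
# "not reached" is a literal token for durations.
CSV_COLUMNS <- c(
  "record_id", "design", "primary_endpoint", "n_subjects",
  "superiority_met", "noninferiority_met",
  "os_gain", "os_gain_unit", "os_control_median_months", "os_hr",
  "os_landmark_gain_pct", "os_landmark_years",
  "pfs_gain", "pfs_gain_unit", "pfs_control_median_months", "pfs_hr",
  "single_arm_pfs_months", "orr_pct", "dcr_pct", "dor_months",
  "dor_statistic", "docb_months", "response_criteria", "best_response",
  "toxicity_ge30pct_grade34", "toxicity_reduced_vs_control",
  "qol_assessed", "qol_improved", "phase4_confirmation", "crossover_penalty",
  "subgroup_label", "entity", "therapy_class", "note")

# Missing cell -> NULL (empty, "(-)" or absent key).
cell_chr <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NULL)
  x <- trimws(as.character(x))
  if (!nzchar(x) || x == "(-)") return(NULL)
  x
}

record_from_row <- function(row) {
  g <- function(name) cell_chr(row[[name]])
  num <- function(name) parse_cell_number(g(name), name)
  unit <- function(name) {
    u <- g(name)
    if (is.null(u) || is.na(u)) "months" else match.arg(tolower(u), c("months", "years"))
  }
  mk_endpoint <- function(kind, prefix) {
    gain <- num(paste0(prefix, "_gain"))
    if (!is.na(gain)) {
      u <- unit(paste0(prefix, "_gain_unit"))
      gain <- sign(gain) * normalize_duration(abs(gain), u)
    }
    hr <- parse_hr_ci(g(paste0(prefix, "_hr")))
    ctrl <- num(paste0(prefix, "_control_median_months"))
    lg <- if (prefix == "os") num("os_landmark_gain_pct") else NA_real_
    ly <- if (prefix == "os") num("os_landmark_years") else NA_real_
    if (is.na(gain) && is.null(hr) && is.na(ctrl) && is.na(lg)) return(NULL)
    survival_endpoint(kind, gain_months = gain, control_median_months = ctrl,
                      hr = hr, landmark_gain_pct = lg,
                      landmark_years = if (is.na(ly)) NA_integer_ else as.integer(ly))
  }
  resp_fields <- c("orr_pct", "dcr_pct", "dor_months", "docb_months",
                   "response_criteria")
  resp <- NULL
  if (any(vapply(resp_fields, function(f) !is.null(cell_chr(row[[f]])), logical(1)))) {
    stat <- g("dor_statistic")
    resp <- response_summary(
      orr_pct = num("orr_pct"), dcr_pct = num("dcr_pct"),
      dor_months = num("dor_months"),
      dor_statistic = if (is.null(stat)) "unspecified" else stat,
      docb_months = num("docb_months"),
      response_criteria = g("response_criteria") %||% NA_character_)
  }
  n <- num("n_subjects")
  design <- g("design")
  if (is.null(design)) stop("field 'design' is required", call. = FALSE)
  study_record(
    record_id = g("record_id") %||% stop("field 'record_id' is required", call. = FALSE),
    design = design,
    primary_endpoint = g("primary_endpoint") %||% "other",
    n_subjects = if (is.na(n)) NA_integer_ else as.integer(n),
    superiority_met = g("superiority_met"),
    noninferiority_met = g("noninferiority_met"),
    os = mk_endpoint("OS", "os"),
    pfs = mk_endpoint("PFS", "pfs"),
    single_arm_pfs_months = num("single_arm_pfs_months"),
    response = resp,
    best_response = g("best_response") %||% NA_character_,
    flags = adjustment_flags(
      toxicity_ge30pct_grade34 = g("toxicity_ge30pct_grade34"),
      toxicity_reduced_vs_control = g("toxicity_reduced_vs_control"),
      qol_assessed = g("qol_assessed"),
      qol_improved = g("qol_improved"),
      phase4_confirmation = g("phase4_confirmation"),
      crossover_penalty = g("crossover_penalty")),
    subgroup_label = g("subgroup_label") %||% NA_character_,
    entity = g("entity") %||% NA_character_,
    therapy_class = g("therapy_class") %||% NA_character_,
    note = g("note") %||% NA_character_)
}

record_to_row <- function(rec) {
  hr_txt <- function(hr) {
    if (is.null(hr)) return(NA_character_)
    sprintf("%s (%s-%s)", format_cell_number(hr$point),
            format_cell_number(hr$lower95), format_cell_number(hr$upper95))
  }
  ep <- function(e, f) if (is.null(e)) NA_real_ else e[[f]]
  r <- rec$response
  data.frame(
    record_id = rec$record_id, design = rec$design,
    primary_endpoint = rec$primary_endpoint,
    n_subjects = ifelse(is.na(rec$n_subjects), NA_character_,
                        as.character(rec$n_subjects)),
    superiority_met = rec$superiority_met,
    noninferiority_met = rec$noninferiority_met,
    os_gain = format_cell_number(ep(rec$os, "gain_months")),
    os_gain_unit = if (is.null(rec$os) || is.na(rec$os$gain_months)) "" else "months",
    os_control_median_months = format_cell_number(ep(rec$os, "control_median_months")),
    os_hr = hr_txt(if (is.null(rec$os)) NULL else rec$os$hr),
    os_landmark_gain_pct = format_cell_number(ep(rec$os, "landmark_gain_pct")),
    os_landmark_years = format_cell_number(ep(rec$os, "landmark_years")),
    pfs_gain = format_cell_number(ep(rec$pfs, "gain_months")),
    pfs_gain_unit = if (is.null(rec$pfs) || is.na(rec$pfs$gain_months)) "" else "months",
    pfs_control_median_months = format_cell_number(ep(rec$pfs, "control_median_months")),
    pfs_hr = hr_txt(if (is.null(rec$pfs)) NULL else rec$pfs$hr),
    single_arm_pfs_months = format_cell_number(rec$single_arm_pfs_months),
    orr_pct = format_cell_number(if (is.null(r)) NA else r$orr_pct),
    dcr_pct = format_cell_number(if (is.null(r)) NA else r$dcr_pct),
    dor_months = format_cell_number(if (is.null(r)) NA else r$dor_months),
    dor_statistic = if (is.null(r)) "" else r$dor_statistic,
    docb_months = format_cell_number(if (is.null(r)) NA else r$docb_months),
    response_criteria = if (is.null(r) || is.na(r$response_criteria)) "" else r$response_criteria,
    best_response = ifelse(is.na(rec$best_response), "", rec$best_response),
    toxicity_ge30pct_grade34 = rec$flags$toxicity_ge30pct_grade34,
    toxicity_reduced_vs_control = rec$flags$toxicity_reduced_vs_control,
    qol_assessed = rec$flags$qol_assessed,
    qol_improved = rec$flags$qol_improved,
    phase4_confirmation = rec$flags$phase4_confirmation,
    crossover_penalty = rec$flags$crossover_penalty,
    subgroup_label = ifelse(is.na(rec$subgroup_label), "", rec$subgroup_label),
    entity = ifelse(is.na(rec$entity), "", rec$entity),
    therapy_class = ifelse(is.na(rec$therapy_class), "", rec$therapy_class),
    note = ifelse(is.na(rec$note), "", rec$note),
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load study records from CSV or JSON
#'
#' The CSV schema is one row per scoring unit with the field names of the
#' domain types (see the packaged JSON-Schema document,
#' `system.file("extdata", "study_record.schema.json", package = "neuromcbs")`).
#' All durations are normalized to months at load; every returned record has
#' passed the type invariants. Rows failing validation are reported together
#' in a single error listing each offending `record_id`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A list of [study_record()] objects in file order. Columns outside
#'   the schema are preserved in the `"extra"` attribute as a data.frame.
#' @export
read_study_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
    if (nrow(df) == 0) return(structure(list(), extra = df))
    rows <- split(df, seq_len(nrow(df)))
  } else {
    objs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(objs) == 0) return(structure(list(), extra = NULL))
    rows <- lapply(objs, json_to_row)
  }
  errors <- list(); records <- list()
  for (i in seq_along(rows)) {
    rec <- tryCatch(record_from_row(as.list(rows[[i]])), error = function(e) e)
    if (inherits(rec, "error")) {
      id <- cell_chr(rows[[i]][["record_id"]]) %||% sprintf("row %d", i)
      errors[[length(errors) + 1]] <-
        sprintf("record '%s': %s", id, conditionMessage(rec))
    } else {
      records[[length(records) + 1]] <- rec
    }
  }
  if (length(errors) > 0) {
    stop(structure(class = c("mcbs_validation_error", "error", "condition"),
                   list(message = paste0("invalid records:\n  ",
                                         paste(unlist(errors), collapse = "\n  ")),
                        call = NULL, errors = unlist(errors))))
  }
  extra <- NULL
  if (format == "csv") {
    extra_cols <- setdiff(names(df), CSV_COLUMNS)
    if (length(extra_cols) > 0) extra <- df[, c("record_id", extra_cols), drop = FALSE]
  }
  structure(records, extra = extra)
}

# Flatten one JSON record object (nested os/pfs/response/flags) into the flat
# row vocabulary shared with the CSV path.
json_to_row <- function(obj) {
  row <- list()
  scalars <- c("record_id", "design", "primary_endpoint", "n_subjects",
               "superiority_met", "noninferiority_met", "single_arm_pfs_months",
               "best_response", "subgroup_label", "entity", "therapy_class", "note")
  for (f in scalars) row[[f]] <- obj[[f]]
  for (prefix in c("os", "pfs")) {
    e <- obj[[prefix]]
    if (!is.null(e)) {
      row[[paste0(prefix, "_gain")]] <- e$gain_months
      row[[paste0(prefix, "_gain_unit")]] <- "months"
      row[[paste0(prefix, "_control_median_months")]] <- e$control_median_months
      if (!is.null(e$hr)) {
        row[[paste0(prefix, "_hr")]] <- sprintf("%s (%s-%s)", e$hr$point,
                                                e$hr$lower95, e$hr$upper95)
      }
      if (prefix == "os") {
        row$os_landmark_gain_pct <- e$landmark_gain_pct
        row$os_landmark_years <- e$landmark_years
      }
    }
  }
  r <- obj$response
  if (!is.null(r)) {
    for (f in c("orr_pct", "dcr_pct", "dor_months", "dor_statistic",
                "docb_months", "response_criteria")) row[[f]] <- r[[f]]
  }
  fl <- obj$flags
  if (!is.null(fl)) for (f in names(fl)) row[[f]] <- fl[[f]]
  row
}

record_to_json_obj <- function(rec) {
  ep <- function(e) {
    if (is.null(e)) return(NULL)
    out <- compact(list(
      endpoint_kind = e$endpoint_kind,
      gain_months = if (is.na(e$gain_months)) NULL else unbox_num(e$gain_months),
      control_median_months = if (is.na(e$control_median_months)) NULL else e$control_median_months,
      hr = if (is.null(e$hr)) NULL else list(point = e$hr$point,
                                             lower95 = e$hr$lower95,
                                             upper95 = e$hr$upper95),
      landmark_gain_pct = if (is.na(e$landmark_gain_pct)) NULL else e$landmark_gain_pct,
      landmark_years = if (is.na(e$landmark_years)) NULL else e$landmark_years))
    out
  }
  r <- rec$response
  compact(list(
    record_id = rec$record_id, design = rec$design,
    primary_endpoint = rec$primary_endpoint,
    n_subjects = if (is.na(rec$n_subjects)) NULL else rec$n_subjects,
    superiority_met = rec$superiority_met,
    noninferiority_met = rec$noninferiority_met,
    os = ep(rec$os), pfs = ep(rec$pfs),
    single_arm_pfs_months = if (is.na(rec$single_arm_pfs_months)) NULL else rec$single_arm_pfs_months,
    response = if (is.null(r)) NULL else compact(list(
      orr_pct = if (is.na(r$orr_pct)) NULL else r$orr_pct,
      dcr_pct = if (is.na(r$dcr_pct)) NULL else r$dcr_pct,
      dor_months = if (is.na(r$dor_months)) NULL else unbox_num(r$dor_months),
      dor_statistic = r$dor_statistic,
      docb_months = if (is.na(r$docb_months)) NULL else unbox_num(r$docb_months),
      response_criteria = if (is.na(r$response_criteria)) NULL else r$response_criteria)),
    best_response = if (is.na(rec$best_response)) NULL else rec$best_response,
    flags = unclass(rec$flags),
    subgroup_label = if (is.na(rec$subgroup_label)) NULL else rec$subgroup_label,
    entity = if (is.na(rec$entity)) NULL else rec$entity,
    therapy_class = if (is.na(rec$therapy_class)) NULL else rec$therapy_class,
    note = if (is.na(rec$note)) NULL else rec$note))
}

# Inf must round-trip through JSON; encode as the file-format token.
unbox_num <- function(x) if (is.infinite(x)) "not reached" else x

#' Write study records to CSV or JSON
#'
#' Inverse of [read_study_records()]: a write-then-read round trip preserves
#' every field, including missing values and "not reached" duration tokens.
#'
#' @param records list of [study_record()] objects.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_study_records <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    rows <- lapply(records, record_to_row)
    df <- if (length(rows) == 0) {
      as.data.frame(setNames(rep(list(character(0)), length(CSV_COLUMNS)),
                             CSV_COLUMNS), check.names = FALSE)
    } else do.call(rbind, rows)
    df[is.na(df)] <- ""
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(lapply(records, record_to_json_obj), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
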
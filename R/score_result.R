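FORM_MAX <- c(form2a = 5L, form2b = 4L, form2c = 4L, form3 = 4L,
              neuro_mcbs = 4L, asco_advanced = 130L, asco_adjuvant = 100L)

NA_REASONS <- c("insufficient_toxicity_data", "noninferiority_design_unsupported",
                "no_statistical_significance", "duration_of_response_missing",
                "control_median_required", "all_criteria_indeterminate")

new_score <- function(scale_id, form_id, record_id,
                      status = c("scored", "not_assessable"),
                      not_assessable_reason = NA_character_,
                      preliminary = NA_integer_,
                      adjustments = list(),
                      band_used = NA_character_,
                      audit = list(), notes = character(0)) {
  status <- match.arg(status)
  form_id <- match.arg(form_id, names(FORM_MAX))
  max_score <- FORM_MAX[[form_id]]
  final <- NA_integer_
  if (status == "scored") {
    deltas <- if (length(adjustments)) sum(vapply(adjustments, `[[`, numeric(1), "delta")) else 0
    final <- as.integer(min(max(preliminary + deltas, 0), max_score))
  } else {
    not_assessable_reason <- match.arg(not_assessable_reason, NA_REASONS)
  }
  structure(list(scale_id = scale_id, form_id = form_id, record_id = record_id,
                 status = status, not_assessable_reason = not_assessable_reason,
                 preliminary = preliminary, adjustments = adjustments,
                 final = final, max_score = max_score, band_used = band_used,
                 audit = audit, notes = notes),
            class = "mcbs_score")
}

not_assessable <- function(scale_id, form_id, record_id, reason,
                           audit = list(), notes = character(0)) {
  new_score(scale_id, form_id, record_id, status = "not_assessable",
            not_assessable_reason = reason, audit = audit, notes = notes)
}

adjustment <- function(kind, delta) list(kind = kind, delta = delta)

#' @export
print.mcbs_score <- function(x, ...) {
  cat(sprintf("<%s / %s> record %s\n", x$scale_id, x$form_id, x$record_id))
  if (x$status == "not_assessable") {
    cat("  not assessable:", x$not_assessable_reason, "\n")
  } else {
    cat(sprintf("  preliminary %d", x$preliminary))
    if (length(x$adjustments)) {
      adj <- vapply(x$adjustments, function(a)
        sprintf("%s (%+d)", a$kind, as.integer(a$delta)), character(1))
      cat(",", paste(adj, collapse = ", "))
    }
    cat(sprintf(" -> final %d (max %d)\n", x$final, x$max_score))
  }
  if (!is.na(x$band_used)) cat("  band:", x$band_used, "\n")
  satisfied <- Filter(function(ev) isTRUE(ev$satisfied), x$audit)
  for (ev in satisfied) {
    cat(sprintf("  fired grade %d: %s\n", ev$criterion$grade, ev$criterion$label))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Tabulate a list of score results
#'
#' @param x list of `mcbs_score` objects (as returned by the `score_*`
#'   functions or [score_records()]).
#' @param ... unused.
#' @return data.frame with one row per result (record_id, scale, form, status,
#'   reason, preliminary, adjustment sum, final).
#' @export
scores_as_df <- function(x, ...) {
  rows <- lapply(x, function(s) {
    data.frame(record_id = s$record_id, scale_id = s$scale_id,
               form_id = s$form_id, status = s$status,
               not_assessable_reason = s$not_assessable_reason,
               preliminary = s$preliminary,
               adjustment = if (length(s$adjustments))
                 sum(vapply(s$adjustments, `[[`, numeric(1), "delta")) else 0,
               final = s$final, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
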
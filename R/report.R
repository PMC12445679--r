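# Human-readable score reports with full audit trails. These scales are
# contested, so a score is never emitted without the criterion text that
# produced it.

#' Render a markdown report for a list of score results
#'
#' @param scores list of `mcbs_score` objects.
#' @param title report heading.
#' @return Character vector of markdown lines: one audit section per record
#'   (form applied, preliminary grade, each adjustment, fired criteria with
#'   the input values and proxies used, band) plus a summary table. Every
#'   number traces to a score-result field.
#' @export
render_report <- function(scores, title = "Clinical benefit score report") {
  lines <- c(paste("#", title), "")
  for (s in scores) {
    lines <- c(lines, sprintf("## %s", s$record_id),
               sprintf("- scale: %s (%s)", s$scale_id, s$form_id))
    if (s$status == "not_assessable") {
      lines <- c(lines, sprintf("- **not assessable**: %s", s$not_assessable_reason))
    } else {
      lines <- c(lines, sprintf("- preliminary score: %s", s$preliminary))
      for (a in s$adjustments) {
        lines <- c(lines, sprintf("- adjustment: %s (%+g)", a$kind, a$delta))
      }
      lines <- c(lines, sprintf("- **final score: %g** (maximum %g)",
                                s$final, s$max_score))
    }
    if (!is.na(s$band_used)) lines <- c(lines, sprintf("- band: %s", s$band_used))
    fired <- Filter(function(ev) inherits(ev, "criterion_evaluation") &&
                      isTRUE(ev$satisfied), s$audit)
    for (ev in fired) {
      vals <- vapply(ev$inputs_used, function(inp) {
        sprintf("%s = %s%s", inp$metric, format_cell_number(inp$value),
                if (inp$proxy) " (proxy)" else "")
      }, character(1))
      lines <- c(lines, sprintf("- fired (grade %d): %s [%s]",
                                ev$criterion$grade, ev$criterion$label,
                                paste(vals, collapse = ", ")))
    }
    for (n in s$notes) lines <- c(lines, sprintf("- note: %s", n))
    lines <- c(lines, "")
  }
  df <- scores_as_df(scores)
  lines <- c(lines, "## Summary", "",
             "| record | form | status | preliminary | final |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %s |",
                     df$record_id, df$form_id,
                     ifelse(df$status == "scored", "scored", df$not_assessable_reason),
                     ifelse(is.na(df$preliminary), "-", df$preliminary),
                     ifelse(is.na(df$final), "-", df$final)))
  lines
}

#' Score a record file and write machine- and human-readable outputs
#'
#' The engine behind the command-line `score` subcommand. Not-assessable
#' records are results, not failures; only unreadable input or schema
#' violations raise an error.
#'
#' @param input path to a CSV or JSON record file.
#' @param scale `"neuro"`, `"esmo"` or `"both"`.
#' @param policy a [proxy_policy()].
#' @param out_json optional path for the JSON score table.
#' @param out_report optional path for the markdown audit report.
#' @return Invisibly, a list with `records`, `scores` and the summary
#'   data.frame `table`.
#' @export
run_score <- function(input, scale = c("neuro", "esmo", "both"),
                      policy = proxy_policy(), out_json = NULL,
                      out_report = NULL) {
  scale <- match.arg(scale)
  records <- read_study_records(input)
  scores <- score_records(records, scale = scale, policy = policy)
  flat <- if (scale == "both") c(scores$neuro, scores$esmo) else scores
  table <- if (length(flat)) scores_as_df(flat) else
    data.frame(record_id = character(0), scale_id = character(0),
               form_id = character(0), status = character(0),
               not_assessable_reason = character(0), preliminary = integer(0),
               adjustment = numeric(0), final = integer(0))
  if (!is.null(out_json)) {
    jsonlite::write_json(table, out_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(out_report)) {
    writeLines(render_report(flat), out_report)
  }
  invisible(list(records = records, scores = flat, table = table))
}
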
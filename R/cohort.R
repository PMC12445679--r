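# Cohort-level aggregation of n-of-1 scores: per-entity benefit fractions and
# therapy-class tabulations.

#' Score an n-of-1 cohort and collect a per-patient table
#'
#' @param records list of `patient_n_of_1` [study_record()] objects.
#' @param policy a [proxy_policy()].
#' @param tables grade-table registry.
#' @return data.frame with `record_id`, `entity`, `therapy_class`, `status`,
#'   `final` (NA when not assessable).
#' @export
score_cohort <- function(records, policy = proxy_policy(),
                         tables = mcbs_tables()) {
  scores <- lapply(records, score_patient, policy = policy, tables = tables,
                   audit = FALSE)
  data.frame(
    record_id = vapply(records, `[[`, character(1), "record_id"),
    entity = vapply(records, `[[`, character(1), "entity"),
    therapy_class = vapply(records, `[[`, character(1), "therapy_class"),
    status = vapply(scores, `[[`, character(1), "status"),
    final = vapply(scores, `[[`, integer(1), "final"),
    stringsAsFactors = FALSE)
}

#' Per-entity benefit summary
#'
#' For each tumor entity, counts the scored patients reaching the benefit
#' threshold and reports the percentage with half-up rounding (5/8 prints as
#' 63%, 1/8 as 13%). Not-assessable results are excluded from the
#' denominator and counted separately.
#'
#' @param scores a data.frame as returned by [score_cohort()] (columns
#'   `entity`, `status`, `final`), or a list of `mcbs_score` objects together
#'   with `entities`.
#' @param entities character vector of entities, parallel to `scores`, when
#'   `scores` is a list.
#' @param threshold benefit threshold on the final score (default 3: a
#'   Neuro-MCBS score of 3 or more counts as net clinical benefit).
#' @return data.frame of class `cohort_summary`, one row per entity in
#'   alphabetical order: `entity`, `n_total`, `n_benefit`, `pct_benefit`
#'   (integer percent, NA for an empty cohort), `n_not_assessable`.
#' @export
summarize_cohort <- function(scores, entities = NULL, threshold = 3) {
  if (!is.data.frame(scores)) {
    stopifnot(!is.null(entities), length(entities) == length(scores))
    scores <- data.frame(
      entity = as.character(entities),
      status = vapply(scores, `[[`, character(1), "status"),
      final = vapply(scores, function(s) as.double(s$final %||% NA_real_),
                     numeric(1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(scores$entity)), function(ent) {
    sub <- scores[scores$entity == ent, , drop = FALSE]
    scored <- sub[sub$status == "scored", , drop = FALSE]
    n_total <- nrow(scored)
    n_benefit <- sum(scored$final >= threshold)
    data.frame(entity = ent, n_total = n_total, n_benefit = n_benefit,
               pct_benefit = if (n_total > 0)
                 as.integer(round_half_up(100 * n_benefit / n_total)) else NA_integer_,
               n_not_assessable = sum(sub$status == "not_assessable"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(entity = character(0), n_total = integer(0),
                      n_benefit = integer(0), pct_benefit = integer(0),
                      n_not_assessable = integer(0))
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort benefit summary (score >= %d):\n", attr(x, "threshold")))
  df <- as.data.frame(x)
  df$pct_benefit <- ifelse(is.na(df$pct_benefit), "-",
                           paste0(df$pct_benefit, "%"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate therapy classes across a cohort
#'
#' @param records list of [study_record()] objects carrying `therapy_class`
#'   labels (unlabeled records are dropped).
#' @return data.frame (`therapy_class`, `n`) in descending count order, ties
#'   broken alphabetically; the counts sum to the number of labeled records.
#' @export
tabulate_therapy_classes <- function(records) {
  labels <- vapply(records, `[[`, character(1), "therapy_class")
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) {
    return(data.frame(therapy_class = character(0), n = integer(0)))
  }
  tab <- table(labels)
  df <- data.frame(therapy_class = names(tab), n = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, df$therapy_class), , drop = FALSE]
  rownames(df) <- NULL
  df
}
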
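METRICS <- c("pfs_months", "orr_pct", "dcr_pct", "gain_months", "hr_lower95",
             "landmark_gain_pct", "landmark_years", "dor_months", "docb_months")

#' One row of a graded scale
#'
#' A criterion awards `grade` when its head metric lies in
#' `[lower, upper]`/`[lower, upper)` (per the closed flags) and every companion
#' interval holds jointly, e.g. "DCR >= 20 to < 60% and DoCB >= 9 months" is
#' head `dcr_pct` in `[20, 60)` with companion `docb_months` in `[9, Inf)`.
#'
#' @param grade integer grade awarded (>= 1).
#' @param metric head metric name (one of the engine's metric vocabulary).
#' @param lower,upper interval bounds (default `-Inf`/`Inf`).
#' @param lower_closed,upper_closed bound closedness; the printed convention
#'   ">= a to < b" is the default (closed lower, open upper).
#' @param companions list of further interval conditions, each a list with
#'   fields `metric`, `lower`, `lower_closed`, `upper`, `upper_closed`.
#' @param label optional human-readable criterion text for audit trails.
#' @return An object of class `grade_criterion`.
#' @export
grade_criterion <- function(grade, metric, lower = -Inf, upper = Inf,
                            lower_closed = TRUE, upper_closed = FALSE,
                            companions = list(), label = NULL) {
  metric <- match.arg(metric, METRICS)
  stopifnot(grade >= 1, grade == as.integer(grade))
  if (!(lower < upper || (lower == upper && lower_closed && upper_closed))) {
    stop("criterion interval is empty", call. = FALSE)
  }
  companions <- lapply(companions, function(co) {
    co$metric <- match.arg(co$metric, METRICS)
    if (co$metric == metric) {
      stop("companion metric must differ from the head metric", call. = FALSE)
    }
    list(metric = co$metric,
         lower = co$lower %||% -Inf,
         lower_closed = co$lower_closed %||% TRUE,
         upper = co$upper %||% Inf,
         upper_closed = co$upper_closed %||% FALSE)
  })
  structure(list(grade = as.integer(grade), metric = metric,
                 lower = lower, lower_closed = isTRUE(lower_closed),
                 upper = upper, upper_closed = isTRUE(upper_closed),
                 companions = companions,
                 label = label %||% describe_criterion_parts(metric, lower, lower_closed,
                                                             upper, upper_closed, companions)),
            class = "grade_criterion")
}

describe_interval <- function(metric, lower, lower_closed, upper, upper_closed) {
  lo <- if (is.finite(lower)) sprintf("%s %s", if (lower_closed) ">=" else ">", lower) else NULL
  hi <- if (is.finite(upper)) sprintf("%s %s", if (upper_closed) "<=" else "<", upper) else NULL
  paste0(metric, " ", paste(c(lo, hi), collapse = " and "))
}

describe_criterion_parts <- function(metric, lower, lower_closed, upper,
                                     upper_closed, companions) {
  parts <- c(describe_interval(metric, lower, lower_closed, upper, upper_closed),
             vapply(companions, function(co) {
               describe_interval(co$metric, co$lower, co$lower_closed,
                                 co$upper, co$upper_closed)
             }, character(1)))
  paste(parts, collapse = " with ")
}

#' Declarative graded scale
#'
#' @param table_id unique identifier within the registry (e.g. `"neuro_mcbs_v1"`).
#' @param max_preliminary highest preliminary grade the table can award.
#' @param criteria list of [grade_criterion()] objects; every grade from 1 to
#'   `max_preliminary` must have at least one criterion.
#' @param source citation text for the transcription.
#' @return An object of class `grade_table`.
#' @export
grade_table <- function(table_id, max_preliminary, criteria, source = "") {
  stopifnot(is.character(table_id), length(criteria) > 0)
  grades <- vapply(criteria, function(cr) cr$grade, integer(1))
  missing_grades <- setdiff(seq_len(max_preliminary), grades)
  if (length(missing_grades) > 0) {
    stop(sprintf("table '%s' has no criterion for grade(s) %s", table_id,
                 paste(missing_grades, collapse = ", ")), call. = FALSE)
  }
  structure(list(table_id = table_id,
                 max_preliminary = as.integer(max_preliminary),
                 criteria = criteria, source = source),
            class = "grade_table")
}

#' Evaluate a single criterion against a (possibly partial) value map
#'
#' @param criterion a [grade_criterion()].
#' @param values named list mapping metric names to numbers; a metric may be
#'   absent or `NA` (missing). `Inf` encodes "not reached" durations.
#' @param proxied character vector of metric names whose values were proxy
#'   substitutions (recorded in the audit trail).
#' @return A list of class `criterion_evaluation` with `satisfied`
#'   (`TRUE`/`FALSE`/`NA` for indeterminate), `missing_metrics`, and
#'   `inputs_used` (metric, value, proxy flag per input consulted).
#' @export
evaluate_criterion <- function(criterion, values, proxied = character(0)) {
  parts <- c(list(list(metric = criterion$metric, lower = criterion$lower,
                       lower_closed = criterion$lower_closed,
                       upper = criterion$upper,
                       upper_closed = criterion$upper_closed)),
             criterion$companions)
  status <- logical(0); missing_metrics <- character(0); inputs <- list()
  result <- TRUE
  for (p in parts) {
    v <- values[[p$metric]]
    if (is.null(v) || is.na(v)) {
      missing_metrics <- c(missing_metrics, p$metric)
      status <- c(status, NA)
    } else {
      ok <- in_interval(v, p$lower, p$lower_closed, p$upper, p$upper_closed)
      status <- c(status, ok)
      inputs[[length(inputs) + 1]] <- list(metric = p$metric, value = v,
                                           proxy = p$metric %in% proxied)
    }
  }
  satisfied <- if (any(!status, na.rm = TRUE)) FALSE else if (anyNA(status)) NA else TRUE
  structure(list(criterion = criterion, satisfied = satisfied,
                 missing_metrics = if (is.na(satisfied)) missing_metrics else character(0),
                 inputs_used = inputs),
            class = "criterion_evaluation")
}

#' Preliminary grade: highest criterion fulfilled
#'
#' The ESMO convention applied throughout: the preliminary grade is the
#' maximum grade among satisfied criteria. When no criterion is satisfied but
#' at least one was determinate, the grade is 0 ("no demonstrable benefit",
#' distinct from not assessable); when every criterion is indeterminate the
#' result is not assessable.
#'
#' @param table a [grade_table()].
#' @param values named metric->value list (see [evaluate_criterion()]).
#' @param proxied metric names filled in by proxy substitution.
#' @param audit if `FALSE`, skip building the per-criterion audit list (used in
#'   large simulated cohorts).
#' @return List with `grade` (integer, or `NA` when not assessable),
#'   `assessable` (logical), `missing_metrics` (metrics whose absence left
#'   criteria indeterminate), `indeterminate_sets` (per indeterminate
#'   criterion, the set of missing metrics that blocked it) and `fired` (all
#'   criterion evaluations).
#' @export
preliminary_grade <- function(table, values, proxied = character(0), audit = TRUE) {
  best <- 0L; any_determinate <- FALSE
  missing_metrics <- character(0); indeterminate_sets <- list()
  fired <- if (audit) vector("list", length(table$criteria))
  for (i in seq_along(table$criteria)) {
    ev <- evaluate_criterion(table$criteria[[i]], values, proxied)
    if (audit) fired[[i]] <- ev
    if (is.na(ev$satisfied)) {
      missing_metrics <- union(missing_metrics, ev$missing_metrics)
      indeterminate_sets[[length(indeterminate_sets) + 1]] <- ev$missing_metrics
    } else {
      any_determinate <- TRUE
      if (ev$satisfied && ev$criterion$grade > best) best <- ev$criterion$grade
    }
  }
  if (!any_determinate) {
    return(list(grade = NA_integer_, assessable = FALSE,
                missing_metrics = missing_metrics,
                indeterminate_sets = indeterminate_sets, fired = fired))
  }
  list(grade = best, assessable = TRUE, missing_metrics = missing_metrics,
       indeterminate_sets = indeterminate_sets, fired = fired)
}

# ---- registry ---------------------------------------------------------------

.registry_cache <- new.env(parent = emptyenv())

parse_table_spec <- function(spec) {
  criteria <- lapply(spec$criteria, function(cr) {
    grade_criterion(grade = cr$grade, metric = cr$metric,
                    lower = cr$lower %||% -Inf, upper = cr$upper %||% Inf,
                    lower_closed = cr$lower_closed %||% TRUE,
                    upper_closed = cr$upper_closed %||% FALSE,
                    companions = cr$companions %||% list(),
                    label = cr$label)
  })
  grade_table(spec$table_id, spec$max_preliminary, criteria,
              source = spec$source %||% "")
}

#' Load the packaged grade-table registry
#'
#' The scales are data, not code: each ESMO form band and the Neuro-MCBS table
#' ships as a declarative YAML document with a source citation, evaluated by
#' the generic engine. Supplying `path` loads an alternative registry.
#'
#' @param path optional path to a registry YAML file; defaults to the packaged
#'   registry.
#' @return Named list of [grade_table()] objects keyed by `table_id`.
#' @export
mcbs_tables <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.registry_cache$tables)) return(.registry_cache$tables)
  if (is.null(path)) {
    path <- system.file("extdata", "grade_tables.yaml", package = "neuromcbs")
  }
  doc <- yaml::read_yaml(path)
  tables <- lapply(doc$tables, parse_table_spec)
  ids <- vapply(tables, function(tb) tb$table_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate table_id in registry", call. = FALSE)
  names(tables) <- ids
  if (default) .registry_cache$tables <- tables
  tables
}

#' @export
print.grade_table <- function(x, ...) {
  cat(sprintf("<grade_table %s> max preliminary %d\n", x$table_id,
              x$max_preliminary))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  for (cr in x$criteria) cat(sprintf("  grade %d: %s\n", cr$grade, cr$label))
  invisible(x)
}

# Drop upper bounds on DCR criteria ("monotone" policy mode): a disease-control
# rate above a band's printed ceiling then still earns that band's grade.
monotonize_table <- function(table) {
  table$criteria <- lapply(table$criteria, function(cr) {
    if (cr$metric == "dcr_pct") {
      cr$upper <- Inf; cr$upper_closed <- FALSE
      cr$label <- describe_criterion_parts(cr$metric, cr$lower, cr$lower_closed,
                                           Inf, FALSE, cr$companions)
    }
    cr
  })
  table$table_id <- paste0(table$table_id, "_monotone")
  table
}
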
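# Independent oracles used across the suite. Both are deliberately
# straight-line re-implementations that share no code with the engine.

# Direct transcription of the single-arm benefit scale, steps 1-3: preliminary
# grade from PFS / ORR / DCR / DoCB, toxicity downgrade, QoL or phase-4
# upgrade, cap 4, floor 0. Inputs already proxy-resolved; NA means missing.
oracle_neuro_score <- function(pfs = NA, orr = NA, dcr = NA, docb = NA,
                               tox = "no", qol = "no", phase4 = "no") {
  g <- 0
  if (!is.na(pfs) && pfs >= 2 && pfs < 3) g <- max(g, 1)
  if (!is.na(orr) && !is.na(docb) && orr >= 20 && orr < 40 && docb < 6) g <- max(g, 1)
  if (!is.na(dcr) && !is.na(docb) && dcr >= 10 && dcr < 20 && docb >= 6) g <- max(g, 1)
  if (!is.na(pfs) && pfs >= 3 && pfs < 6) g <- max(g, 2)
  if (!is.na(orr) && orr >= 40 && orr < 60) g <- max(g, 2)
  if (!is.na(dcr) && !is.na(docb) && dcr >= 20 && dcr < 40 && docb >= 6 && docb < 9) g <- max(g, 2)
  if (!is.na(pfs) && pfs >= 6) g <- max(g, 3)
  if (!is.na(orr) && orr >= 60) g <- max(g, 3)
  if (!is.na(dcr) && !is.na(docb) && dcr >= 20 && dcr < 60 && docb >= 9) g <- max(g, 3)
  delta <- (qol == "yes" || phase4 == "yes") - (tox == "yes")
  min(max(g + delta, 0), 4)
}

# n-of-1 convention on top of the scale: best response becomes 0/100 rates.
oracle_patient_score <- function(pfs, best, docb = NA, tox = "no", qol = "no") {
  orr <- if (best %in% c("CR", "PR", "MR")) 100 else 0
  dcr <- if (best %in% c("CR", "PR", "MR", "SD")) 100 else 0
  oracle_neuro_score(pfs = pfs, orr = orr, dcr = dcr, docb = docb,
                     tox = tox, qol = qol)
}

# Brute-force preliminary grade: enumerate criteria independently with naive
# comparisons, tracking TRUE/FALSE/missing per criterion.
oracle_preliminary <- function(table, values) {
  sat <- rep(NA, length(table$criteria))
  for (i in seq_along(table$criteria)) {
    cr <- table$criteria[[i]]
    parts <- c(list(list(metric = cr$metric, lower = cr$lower,
                         lower_closed = cr$lower_closed, upper = cr$upper,
                         upper_closed = cr$upper_closed)), cr$companions)
    part_ok <- rep(NA, length(parts))
    for (j in seq_along(parts)) {
      p <- parts[[j]]
      v <- values[[p$metric]]
      if (is.null(v) || is.na(v)) next
      lo_ok <- if (p$lower == -Inf) TRUE
               else if (p$lower_closed) v >= p$lower else v > p$lower
      hi_ok <- if (p$upper == Inf) TRUE
               else if (p$upper_closed) v <= p$upper else v < p$upper
      part_ok[j] <- lo_ok && hi_ok
    }
    sat[i] <- if (any(part_ok %in% FALSE)) FALSE else if (anyNA(part_ok)) NA else TRUE
  }
  if (all(is.na(sat))) return(NA_integer_)
  grades <- vapply(table$criteria, `[[`, integer(1), "grade")
  fired <- grades[which(sat %in% TRUE)]
  if (length(fired) == 0) 0L else max(fired)
}

# Random grade tables and value maps for the evaluator-vs-oracle property.
random_table <- function(max_grade = 3, max_criteria = 12) {
  n <- sample(seq(max_grade, max_criteria), 1)
  grades <- c(seq_len(max_grade), sample(seq_len(max_grade), n - max_grade,
                                         replace = TRUE))
  criteria <- lapply(grades, function(g) {
    metric <- sample(c("pfs_months", "orr_pct", "dcr_pct", "docb_months",
                       "gain_months", "hr_lower95"), 1)
    lo <- sample(c(-Inf, round(stats::runif(1, 0, 50), 1)), 1)
    hi <- sample(c(Inf, max(lo, 0) + round(stats::runif(1, 0.5, 30), 1)), 1)
    comp <- list()
    if (stats::runif(1) < 0.5) {
      cm <- sample(setdiff(c("pfs_months", "orr_pct", "dcr_pct", "docb_months"),
                           metric), 1)
      comp <- list(list(metric = cm, lower = round(stats::runif(1, 0, 12), 1)))
    }
    grade_criterion(g, metric, lower = lo, upper = hi,
                    lower_closed = sample(c(TRUE, FALSE), 1),
                    upper_closed = if (is.finite(hi)) sample(c(TRUE, FALSE), 1) else FALSE,
                    companions = comp)
  })
  grade_table("random", max_grade, criteria)
}

random_values <- function() {
  metrics <- c("pfs_months", "orr_pct", "dcr_pct", "docb_months",
               "gain_months", "hr_lower95")
  present <- metrics[stats::runif(length(metrics)) < 0.7]
  vals <- lapply(present, function(m) {
    if (stats::runif(1) < 0.05) Inf else round(stats::runif(1, 0, 70), 1)
  })
  stats::setNames(vals, present)
}

# Minimal record builders.
single_arm_record <- function(id = "S", pfs = NA_real_, orr = NA_real_,
                              dcr = NA_real_, dor = NA_real_, docb = NA_real_,
                              tox = "unknown", qol = "unknown",
                              phase4 = "unknown", entity = NA_character_) {
  has_resp <- !all(is.na(c(orr, dcr, dor, docb)))
  study_record(
    record_id = id, design = "single_arm", primary_endpoint = "ORR",
    single_arm_pfs_months = pfs,
    response = if (has_resp) response_summary(orr_pct = orr, dcr_pct = dcr,
                                              dor_months = dor,
                                              docb_months = docb) else NULL,
    flags = adjustment_flags(
      toxicity_ge30pct_grade34 = tox,
      qol_assessed = if (qol == "yes") "yes" else "unknown",
      qol_improved = qol, phase4_confirmation = phase4),
    entity = entity)
}

comparative_record <- function(id = "C", gain = NA_real_, hr_text = NULL,
                               control_median = NA_real_, superiority = "yes",
                               endpoint = "OS", qol = "unknown",
                               tox_reduced = "unknown") {
  hr <- if (is.null(hr_text)) NULL else parse_hr_ci(hr_text)
  ep <- survival_endpoint(endpoint, gain_months = gain,
                          control_median_months = control_median, hr = hr)
  study_record(
    record_id = id, design = "comparative_superiority",
    primary_endpoint = endpoint, superiority_met = superiority,
    os = if (endpoint == "OS") ep else NULL,
    pfs = if (endpoint == "PFS") ep else NULL,
    flags = adjustment_flags(toxicity_reduced_vs_control = tox_reduced,
                             qol_assessed = if (qol == "yes") "yes" else "unknown",
                             qol_improved = qol))
}
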
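# Seeded synthetic generator for n-of-1 patient records, emulating the
# structure of a molecular-tumor-board observational cohort (tumor entity,
# targeted-therapy class, PFS, best radiographic response, duration of
# clinical benefit, toxicity and QoL flags). PFS is exponential per entity and
# best response categorical; the simplest models matching what the scales
# consume - no claim of clinical realism.

THERAPY_CLASSES <- c("EGFR inhibition" = 17, "mTOR inhibition" = 14,
                     "PD-1/PD-L1 inhibition" = 13, "TK inhibition" = 7,
                     "IDH inhibition" = 5, "FGFR inhibition" = 4,
                     "PARP inhibition" = 3, "CDK 4/6 inhibition" = 3,
                     "NTRK inhibition" = 2, "VEGF inhibition" = 2,
                     "Multikinase inhibition" = 1)

#' Configuration for the synthetic n-of-1 cohort generator
#'
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @param n_patients cohort size.
#' @param entity_mix named numeric vector of entity proportions (sum 1).
#' @param pfs_median_months named per-entity median PFS, months (exponential
#'   PFS model).
#' @param response_probs named list: per entity, probabilities for best
#'   response `c(CR, PR, MR, SD, PD)` (each summing to 1).
#' @param docb_meanlog,docb_sdlog log-normal parameters of the duration of
#'   clinical benefit drawn for disease-controlled patients (truncated at the
#'   patient's PFS, since clinical benefit cannot outlast progression).
#' @param tox_rate probability of the >= 30% grade 3-4 toxicity flag.
#' @param qol_improve_rate probability of an objective QoL improvement flag.
#' @param therapy_class_weights named weights for therapy-class labels.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_patients,
                              entity_mix,
                              pfs_median_months,
                              response_probs,
                              docb_meanlog = log(7), docb_sdlog = 0.6,
                              tox_rate = 0.15, qol_improve_rate = 0.05,
                              therapy_class_weights = THERAPY_CLASSES) {
  stopifnot(n_patients >= 0, !is.null(names(entity_mix)))
  if (abs(sum(entity_mix) - 1) > 1e-9) {
    stop("entity_mix proportions must sum to 1", call. = FALSE)
  }
  entities <- names(entity_mix)
  stopifnot(all(entities %in% names(pfs_median_months)),
            all(entities %in% names(response_probs)))
  for (ent in entities) {
    p <- response_probs[[ent]]
    stopifnot(length(p) == 5, all(c("CR", "PR", "MR", "SD", "PD") %in% names(p)))
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("response probabilities for '%s' must sum to 1", ent),
           call. = FALSE)
    }
    if (any(p < 0)) stop("response probabilities must be non-negative", call. = FALSE)
  }
  stopifnot(all(pfs_median_months[entities] > 0),
            tox_rate >= 0, tox_rate <= 1,
            qol_improve_rate >= 0, qol_improve_rate <= 1)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 entity_mix = entity_mix,
                 pfs_median_months = pfs_median_months,
                 response_probs = response_probs,
                 docb_meanlog = docb_meanlog, docb_sdlog = docb_sdlog,
                 tox_rate = tox_rate, qol_improve_rate = qol_improve_rate,
                 therapy_class_weights = therapy_class_weights),
            class = "simulation_config")
}

#' Default configuration emulating a molecular-tumor-board CNS cohort
#'
#' 70 patients split 8 meningioma / 10 brain metastases / 36 glioblastoma /
#' 8 IDH-mutant astrocytoma / 8 other, with therapy classes weighted by the
#' published tabulation. Per-entity PFS medians and response mixes are chosen
#' as clinically plausible for heavily pretreated CNS cohorts (see the methods
#' vignette).
#'
#' @param seed RNG seed.
#' @param n_patients cohort size.
#' @return A [simulation_config()].
#' @export
default_cohort_config <- function(seed = 2022L, n_patients = 70L) {
  resp <- function(cr, pr, mr, sd, pd) c(CR = cr, PR = pr, MR = mr, SD = sd, PD = pd)
  simulation_config(
    seed = seed, n_patients = n_patients,
    entity_mix = c(meningioma = 8, brain_metastases = 10, glioblastoma = 36,
                   idh_mutant_astrocytoma = 8, other = 8) / 70,
    pfs_median_months = c(meningioma = 8, brain_metastases = 7,
                          glioblastoma = 2.5, idh_mutant_astrocytoma = 3.5,
                          other = 4),
    response_probs = list(
      meningioma = resp(0.02, 0.08, 0.15, 0.55, 0.20),
      brain_metastases = resp(0.05, 0.25, 0.10, 0.35, 0.25),
      glioblastoma = resp(0.01, 0.04, 0.05, 0.25, 0.65),
      idh_mutant_astrocytoma = resp(0.01, 0.04, 0.10, 0.40, 0.45),
      other = resp(0.02, 0.08, 0.10, 0.40, 0.40)))
}

# largest-remainder apportionment: deterministic entity counts matching the
# configured proportions as closely as possible
apportion <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic n-of-1 patient cohort
#'
#' Deterministic for a fixed config seed; the caller's RNG state is left
#' untouched. Every generated record passes the study-record validators.
#'
#' @param config a [simulation_config()].
#' @return List of `patient_n_of_1` [study_record()] objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0) return(list())
  counts <- apportion(config$entity_mix, n)
  entity <- rep(names(config$entity_mix), counts)
  classes <- sample(names(config$therapy_class_weights), n, replace = TRUE,
                    prob = config$therapy_class_weights)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    ent <- entity[i]
    pfs <- stats::rexp(1, rate = log(2) / config$pfs_median_months[[ent]])
    best <- sample(c("CR", "PR", "MR", "SD", "PD"), 1,
                   prob = config$response_probs[[ent]][c("CR", "PR", "MR", "SD", "PD")])
    docb <- NA_real_
    if (best != "PD") {
      docb <- min(stats::rlnorm(1, config$docb_meanlog, config$docb_sdlog), pfs)
    }
    tox <- if (stats::runif(1) < config$tox_rate) "yes" else "no"
    qol <- if (stats::runif(1) < config$qol_improve_rate) "yes" else "no"
    records[[i]] <- study_record(
      record_id = sprintf("SIM-%04d", i),
      design = "patient_n_of_1", primary_endpoint = "other",
      single_arm_pfs_months = pfs,
      best_response = best,
      response = if (is.na(docb)) NULL else response_summary(docb_months = docb),
      flags = adjustment_flags(toxicity_ge30pct_grade34 = tox,
                               qol_assessed = if (qol == "yes") "yes" else "no",
                               qol_improved = qol),
      entity = ent, therapy_class = classes[i])
  }
  records
}
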
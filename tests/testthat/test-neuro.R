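t2 <- load_fixture("table2_single_arm")
t2_by_id <- setNames(t2, vapply(t2, `[[`, character(1), "record_id"))

test_that("the single-arm fixture reproduces every published score", {
  scores <- score_records(t2, "neuro")
  exp <- attr(t2, "expected")$expected_neuro
  for (i in seq_along(scores)) {
    want <- parse_expected(exp[i])
    expect_equal(scores[[i]]$status, want$status, info = scores[[i]]$record_id)
    if (want$status == "scored") {
      expect_equal(scores[[i]]$final, want$final, info = scores[[i]]$record_id)
    } else {
      expect_equal(scores[[i]]$not_assessable_reason, want$reason)
    }
  }
})

test_that("proxy substitutions are applied and audited", {
  # the high-grade basket cohort reaches preliminary 3 only through the
  # ORR->DCR and DoR->DoCB proxies, then loses one level to toxicity
  res <- score_neuro_mcbs(t2_by_id$ROAR_HGG)
  expect_equal(res$preliminary, 3L)
  expect_equal(res$final, 2L)
  expect_match(paste(res$notes, collapse = "; "), "ORR used as lower bound")
  expect_match(paste(res$notes, collapse = "; "), "DoR .* used for missing DoCB")
  proxy_inputs <- unlist(lapply(res$audit, function(ev)
    vapply(ev$inputs_used, `[[`, logical(1), "proxy")))
  expect_true(any(proxy_inputs))
  # with proxies disabled the record cannot reach the DCR rows
  strict <- proxy_policy(allow_orr_as_dcr_floor = FALSE, allow_dor_as_docb = FALSE)
  res_strict <- score_neuro_mcbs(t2_by_id$ROAR_HGG, policy = strict)
  expect_equal(res_strict$preliminary, 2L)  # PFS 4.5 months only
})

test_that("the ORR-as-DCR proxy never lowers a score", {
  set.seed(402)
  for (rep in 1:100) {
    rec <- single_arm_record(
      pfs = if (runif(1) < 0.5) round(runif(1, 0, 16), 1) else NA_real_,
      orr = round(runif(1, 0, 100)), docb = round(runif(1, 0, 18), 1))
    with_proxy <- score_neuro_mcbs(rec, audit = FALSE)
    without <- score_neuro_mcbs(rec, policy = proxy_policy(allow_orr_as_dcr_floor = FALSE),
                                audit = FALSE)
    if (with_proxy$status == "scored" && without$status == "scored") {
      expect_gte(with_proxy$final, without$final)
    }
  }
})

test_that("toxicity downgrade and QoL upgrade cancel exactly", {
  base <- score_neuro_mcbs(single_arm_record(pfs = 7))$final
  both <- score_neuro_mcbs(single_arm_record(pfs = 7, tox = "yes", qol = "yes"))
  expect_equal(both$final, base)
  expect_length(both$adjustments, 2)
  expect_equal(sum(vapply(both$adjustments, `[[`, numeric(1), "delta")), 0)
})

test_that("the upgrade is a single +1 even when QoL and phase-4 both hold", {
  res <- score_neuro_mcbs(single_arm_record(pfs = 4, qol = "yes", phase4 = "yes"))
  expect_equal(res$final, 3L)
  expect_length(res$adjustments, 1)
  # phase-4 experience alone also upgrades
  res_p4 <- score_neuro_mcbs(single_arm_record(pfs = 4, phase4 = "yes"))
  expect_equal(res_p4$final, 3L)
  expect_equal(res_p4$adjustments[[1]]$kind, "phase4_upgrade")
})

test_that("scores floor at 0 and a downgrade may take a preliminary 1 there", {
  res <- score_neuro_mcbs(single_arm_record(pfs = 2.4, tox = "yes"))
  expect_equal(res$preliminary, 1L)
  expect_equal(res$final, 0L)
  expect_equal(res$status, "scored")
  # below every band with everything reported: scored 0, not n/a
  res0 <- score_neuro_mcbs(single_arm_record(pfs = 1, orr = 5, dcr = 8))
  expect_equal(res0$final, 0L)
  expect_equal(res0$status, "scored")
})

test_that("unknown flags block upgrades but trigger no downgrade", {
  res <- score_neuro_mcbs(single_arm_record(pfs = 7, tox = "unknown",
                                            qol = "unknown"))
  expect_length(res$adjustments, 0)
  expect_equal(res$final, 3L)
})

test_that("as-printed DCR bands are literal; monotone mode repairs them", {
  rec <- single_arm_record(orr = 10, dcr = 70, docb = 12)
  expect_warning(res <- score_neuro_mcbs(rec), "exceeds the printed band")
  expect_equal(res$final, 0L)  # DCR 70 overshoots every printed DCR band
  mono <- score_neuro_mcbs(rec, policy = proxy_policy(dcr_band_mode = "monotone"))
  expect_equal(mono$final, 3L)
  # monotone mode: score non-decreasing in DCR
  finals <- vapply(seq(0, 100, by = 5), function(dcr) {
    score_neuro_mcbs(single_arm_record(dcr = dcr, docb = 12),
                     policy = proxy_policy(dcr_band_mode = "monotone"),
                     audit = FALSE)$final
  }, integer(1))
  expect_true(all(diff(finals) >= 0))
  # as-printed mode is monotone below the 60% ceiling
  finals_printed <- vapply(seq(0, 59, by = 3), function(dcr) {
    score_neuro_mcbs(single_arm_record(dcr = dcr, docb = 12),
                     audit = FALSE)$final
  }, integer(1))
  expect_true(all(diff(finals_printed) >= 0))
})

test_that("preliminary grade is monotone in PFS and ORR", {
  for (orr in c(NA, 10, 30, 50, 70)) {
    finals <- vapply(c(1, 2, 2.9, 3, 5.9, 6, 14), function(pfs)
      score_neuro_mcbs(single_arm_record(pfs = pfs, orr = orr, docb = 10),
                       audit = FALSE)$preliminary, integer(1))
    expect_true(all(diff(finals) >= 0))
  }
  finals_orr <- vapply(c(5, 15, 25, 45, 65, 95), function(orr)
    score_neuro_mcbs(single_arm_record(pfs = 1, orr = orr, docb = 10),
                     audit = FALSE)$preliminary, integer(1))
  expect_true(all(diff(finals_orr) >= 0))
})

test_that("n-of-1 patients are scored by the Table-3 convention", {
  pt <- function(pfs, best, docb = NA_real_, tox = "no", qol = "no") {
    study_record("P", "patient_n_of_1", single_arm_pfs_months = pfs,
                 best_response = best,
                 response = if (is.na(docb)) NULL else
                   response_summary(docb_months = docb),
                 flags = adjustment_flags(toxicity_ge30pct_grade34 = tox,
                                          qol_assessed = if (qol == "yes") "yes" else "no",
                                          qol_improved = qol))
  }
  expect_equal(score_patient(pt(7.2, "SD"))$preliminary, 3L)   # PFS >= 6
  expect_equal(score_patient(pt(2.4, "PD"))$preliminary, 1L)   # PFS >= 2 to < 3
  # best response CR/PR/MR maps to ORR 100
  expect_equal(score_patient(pt(1, "PR"))$preliminary, 3L)
  # neither response nor PFS: not assessable
  blank <- study_record("P0", "patient_n_of_1")
  expect_equal(score_patient(blank)$status, "not_assessable")
  expect_error(score_patient(single_arm_record(pfs = 5)), "patient_n_of_1")
  expect_error(score_neuro_mcbs(comparative_record(gain = 3, hr_text = "0.5 (0.4-0.6)")),
               "single-arm designs only")
})

test_that("simulated patients match a straight-line re-implementation of the scale", {
  cohort <- generate_cohort(default_cohort_config(seed = 99, n_patients = 300))
  engine <- vapply(cohort, function(p) score_patient(p, audit = FALSE)$final,
                   integer(1))
  byhand <- vapply(cohort, function(p) {
    docb <- if (is.null(p$response)) NA_real_ else p$response$docb_months
    oracle_patient_score(p$single_arm_pfs_months, p$best_response, docb,
                         tox = p$flags$toxicity_ge30pct_grade34,
                         qol = p$flags$qol_improved)
  }, numeric(1))
  expect_equal(engine, as.integer(byhand))
})

test_that("final Neuro-MCBS scores never exceed 4", {
  set.seed(403)
  for (rep in 1:200) {
    rec <- single_arm_record(
      pfs = round(runif(1, 0, 20), 1), orr = round(runif(1, 0, 100)),
      docb = round(runif(1, 0, 24), 1),
      tox = sample(c("yes", "no", "unknown"), 1),
      qol = sample(c("yes", "no", "unknown"), 1),
      phase4 = sample(c("yes", "no", "unknown"), 1))
    res <- score_neuro_mcbs(rec, audit = FALSE)
    expect_true(res$final >= 0 && res$final <= 4)
  }
})
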
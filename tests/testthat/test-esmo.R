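tables <- mcbs_tables()
t1 <- load_fixture("table1_comparative")
t1_by_id <- setNames(t1, vapply(t1, `[[`, character(1), "record_id"))

test_that("form routing follows design and primary endpoint", {
  expect_equal(select_form(t1_by_id$EF14), "form2a")       # OS benefit promotes PFS-primary
  expect_equal(select_form(t1_by_id$INDIGO), "form2b")     # PFS primary, no OS data
  expect_equal(select_form(t1_by_id$NOA08), "form2c")      # non-inferiority design
  expect_equal(select_form(t1_by_id$EORTC26981), "form2a") # OS primary
  expect_equal(select_form(single_arm_record(orr = 20)), "form3")
  expect_equal(select_form(study_record("P", "patient_n_of_1",
                                        single_arm_pfs_months = 4)), "form3")
  routed <- vapply(t1, select_form, character(1))
  expect_equal(routed, attr(t1, "expected")$expected_form)
})

test_that("scoring the comparative fixture reproduces every published score and n/a", {
  scores <- score_records(t1, "esmo")
  exp <- attr(t1, "expected")$expected_esmo
  for (i in seq_along(scores)) {
    want <- parse_expected(exp[i])
    expect_equal(scores[[i]]$status, want$status, info = scores[[i]]$record_id)
    if (want$status == "scored") {
      expect_equal(scores[[i]]$final, want$final, info = scores[[i]]$record_id)
    } else {
      expect_equal(scores[[i]]$not_assessable_reason, want$reason,
                   info = scores[[i]]$record_id)
    }
  }
})

test_that("form 2a uses the control-median band and the band-invariance shortcut", {
  # identical grade in both bands scores without any control-arm median
  ceteg <- score_form2a(t1_by_id$CETEG)
  expect_equal(ceteg$final, 4L)
  expect_equal(ceteg$band_used, "band_invariant")
  # band-dependent grade without a control median: truthfully not assessable
  band_dep <- comparative_record("BD", gain = 2.7, hr_text = "0.6 (0.55-0.7)")
  res <- score_form2a(band_dep)  # grade 3 in <=12 band, 2 in >12 band
  expect_equal(res$status, "not_assessable")
  expect_equal(res$not_assessable_reason, "control_median_required")
  # the same record scores once the control median fixes the band
  res_lo <- score_form2a(comparative_record("BD", gain = 2.7,
                                            hr_text = "0.6 (0.55-0.7)",
                                            control_median = 10))
  expect_equal(res_lo$final, 3L)
  expect_equal(res_lo$band_used, "le_threshold")
  res_hi <- score_form2a(comparative_record("BD", gain = 2.7,
                                            hr_text = "0.6 (0.55-0.7)",
                                            control_median = 14))
  expect_equal(res_hi$final, 2L)
  expect_equal(res_hi$band_used, "gt_threshold")
})

test_that("form 2a upgrade adds exactly one point up to the cap of 5", {
  base <- comparative_record("UP", gain = 20, hr_text = "0.5 (0.4-0.6)")
  expect_equal(score_form2a(base)$final, 4L)
  up <- comparative_record("UP", gain = 20, hr_text = "0.5 (0.4-0.6)", qol = "yes")
  res <- score_form2a(up)
  expect_equal(res$final, 5L)
  expect_length(res$adjustments, 1)
  # a second credit (toxicity) does not stack past one upgrade
  up2 <- comparative_record("UP", gain = 20, hr_text = "0.5 (0.4-0.6)",
                            qol = "yes", tox_reduced = "yes")
  expect_equal(score_form2a(up2)$final, 5L)
})

test_that("failed superiority is not assessable, not an error", {
  res <- score_form2a(comparative_record("NS", gain = -1.2,
                                         hr_text = "0.99 (0.53-1.86)",
                                         superiority = "no"))
  expect_equal(res$status, "not_assessable")
  expect_equal(res$not_assessable_reason, "no_statistical_significance")
})

test_that("form 2b caps at 4 across every grade-adjustment combination", {
  grid <- expand.grid(hr = c("0.4 (0.3-0.5)", "0.8 (0.7-0.9)"),
                      gain = c(0.5, 2, 8), qol = c("yes", "no"),
                      penalty = c("yes", "no"), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(grid))) {
    rec <- comparative_record("G", gain = grid$gain[k], hr_text = grid$hr[k],
                              control_median = 5, endpoint = "PFS",
                              qol = grid$qol[k])
    rec$flags$crossover_penalty <- grid$penalty[k]
    res <- score_form2b(rec)
    expect_true(res$final >= 0 && res$final <= 4)
    deltas <- if (length(res$adjustments))
      sum(vapply(res$adjustments, `[[`, numeric(1), "delta")) else 0
    expect_equal(res$final,
                 as.integer(min(max(res$preliminary + deltas, 0), 4)))
  }
})

test_that("form 2c gates non-inferiority on toxicity or QoL evidence", {
  noa <- t1_by_id$NOA08
  res <- score_form2c(noa)
  expect_equal(res$not_assessable_reason, "insufficient_toxicity_data")
  # with positive toxicity evidence the same record scores
  noa$flags$toxicity_reduced_vs_control <- "yes"
  expect_equal(score_form2c(noa)$status, "scored")
  expect_equal(score_form2c(noa)$final, 4L)
  # non-inferiority not met
  noa$noninferiority_met <- "no"
  expect_equal(score_form2c(noa)$not_assessable_reason,
               "no_statistical_significance")
})

test_that("form 3 reproduces the single-arm fixture and its n/a", {
  t2 <- load_fixture("table2_single_arm")
  scores <- score_records(t2, "esmo")
  exp <- attr(t2, "expected")$expected_esmo
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

test_that("form 3 flags a missing duration only when it blocks the grade", {
  # ORR 24 with no DoR and no PFS: the duration was the only path
  res <- score_form3(single_arm_record(orr = 24))
  expect_equal(res$not_assessable_reason, "duration_of_response_missing")
  # same ORR but PFS present: scored through the PFS rows
  expect_equal(score_form3(single_arm_record(pfs = 4, orr = 24))$final, 2L)
  # nothing at all: indeterminate across the board
  res2 <- score_form3(single_arm_record())
  expect_equal(res2$not_assessable_reason, "all_criteria_indeterminate")
})

test_that("comparative preliminary grades are monotone in HR limit and gain", {
  gains <- c(1, 2, 2.6, 3.5, 6, 12)
  lls <- c(0.9, 0.75, 0.7, 0.65, 0.5, 0.3)
  for (tb_id in c("esmo_form2a_le12_v1_1", "esmo_form2a_gt12_v1_1",
                  "esmo_form2b_le6_v1_1", "esmo_form2b_gt6_v1_1")) {
    tb <- tables[[tb_id]]
    for (ll in lls) {
      g <- vapply(gains, function(gain)
        preliminary_grade(tb, list(hr_lower95 = ll, gain_months = gain))$grade,
        integer(1))
      expect_true(all(diff(g) >= 0), info = paste(tb_id, "gain sweep"))
    }
    for (gain in gains) {
      # lls run from 0.9 down to 0.3: an improving (smaller) lower CI limit
      g <- vapply(lls, function(ll)
        preliminary_grade(tb, list(hr_lower95 = ll, gain_months = gain))$grade,
        integer(1))
      expect_true(all(diff(g) >= 0), info = paste(tb_id, "HR sweep"))
    }
  }
})
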
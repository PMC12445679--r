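adv_record <- comparative_record("ADV", gain = 3, hr_text = "0.7 (0.6-0.8)")

test_that("a null-effect hazard ratio earns zero clinical-benefit points", {
  inputs <- asco_inputs("os_hr", hr = hr_estimate(1.0, 0.9, 1.1))
  res <- score_asco(adv_record, inputs, "advanced")
  expect_equal(res$audit$clinical_benefit, 0)
})

test_that("NHB respects the setting caps and decomposes exactly", {
  set.seed(404)
  for (rep in 1:200) {
    hr_point <- runif(1, 0.05, 1.2)
    hr <- hr_estimate(hr_point, hr_point * 0.8, hr_point * 1.2)
    inputs <- asco_inputs(
      sample(c("os_hr", "pfs_hr"), 1), hr = hr,
      toxicity_profile = if (runif(1) < 0.7)
        list(treatment_pct = runif(1, 0, 60), control_pct = runif(1, 0, 60)),
      bonus = list(tail_of_curve = runif(1) < 0.3, palliation = runif(1) < 0.3,
                   qol_improved = runif(1) < 0.3,
                   treatment_free_interval = runif(1) < 0.3))
    for (setting in c("advanced", "adjuvant")) {
      res <- score_asco(adv_record, inputs, setting)
      cap <- if (setting == "advanced") 130 else 100
      expect_lte(res$final, cap)
      expect_equal(res$final, sum(unlist(res$audit)))
      if (setting == "adjuvant") {
        expect_false(any(grepl("^bonus_", names(res$audit))))
      }
    }
  }
})

test_that("NHB is non-increasing in the hazard ratio", {
  hrs <- seq(0.2, 1.1, by = 0.05)
  nhb <- vapply(hrs, function(h) {
    inputs <- asco_inputs("os_hr", hr = hr_estimate(h, h * 0.8, h * 1.2))
    score_asco(adv_record, inputs, "advanced")$final
  }, numeric(1))
  expect_true(all(diff(nhb) <= 0))
  # direct formula check: clinical benefit = (1 - HR) * 100 capped at 80
  inputs <- asco_inputs("os_hr", hr = hr_estimate(0.6, 0.5, 0.7))
  expect_equal(score_asco(adv_record, inputs, "advanced")$audit$clinical_benefit,
               40)
  inputs_deep <- asco_inputs("os_hr", hr = hr_estimate(0.1, 0.05, 0.2))
  expect_equal(score_asco(adv_record, inputs_deep, "advanced")$audit$clinical_benefit,
               80)
})

test_that("non-inferiority designs are unsupported by the framework", {
  ni <- study_record("NI", "comparative_noninferiority", primary_endpoint = "OS",
                     noninferiority_met = "yes",
                     os = survival_endpoint("OS", gain_months = -1,
                                            hr = hr_estimate(1.09, 0.84, 1.42)))
  res <- score_asco(ni, asco_inputs("os_hr", hr = ni$os$hr), "advanced")
  expect_equal(res$status, "not_assessable")
  expect_equal(res$not_assessable_reason, "noninferiority_design_unsupported")
  expect_error(score_asco(single_arm_record(orr = 20),
                          asco_inputs("rr", rr_diff_pct = 10)),
               "randomized comparative")
})

test_that("missing toxicity data excludes the component and flags the result", {
  inputs <- asco_inputs("os_hr", hr = hr_estimate(0.7, 0.6, 0.8))
  res <- score_asco(adv_record, inputs, "advanced")
  expect_false("toxicity" %in% names(res$audit))
  expect_match(paste(res$notes, collapse = " "), "partial")
  # ASCO grades on the point estimate, not the CI limit: two HRs with the
  # same point but different limits score identically
  inputs2 <- asco_inputs("os_hr", hr = hr_estimate(0.7, 0.3, 1.0))
  expect_equal(score_asco(adv_record, inputs2, "advanced")$final, res$final)
})
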
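tables <- mcbs_tables()

test_that("the shipped registry contains every scale with complete grades", {
  expect_setequal(names(tables),
                  c("neuro_mcbs_v1", "esmo_form3_v1_1",
                    "esmo_form2a_le12_v1_1", "esmo_form2a_gt12_v1_1",
                    "esmo_form2b_le6_v1_1", "esmo_form2b_gt6_v1_1"))
  for (tb in tables) {
    grades <- vapply(tb$criteria, `[[`, integer(1), "grade")
    expect_setequal(intersect(seq_len(tb$max_preliminary), grades),
                    seq_len(tb$max_preliminary))
    expect_true(nzchar(tb$source))
  }
})

test_that("criterion evaluation matches printed interval semantics", {
  # PFS >= 6 satisfied by the low-grade glioma cohort's 14 months
  c_pfs6 <- grade_criterion(3, "pfs_months", lower = 6)
  expect_true(evaluate_criterion(c_pfs6, list(pfs_months = 14))$satisfied)
  # companion failure: ORR in-band but duration over the band ceiling
  c_comb <- grade_criterion(2, "orr_pct", lower = 20, upper = 40,
                            companions = list(list(metric = "docb_months",
                                                   lower = 6, upper = 9)))
  ev <- evaluate_criterion(c_comb, list(orr_pct = 31, docb_months = 13.6))
  expect_false(ev$satisfied)
  # missing head metric -> indeterminate, and the gap is reported
  c_band <- grade_criterion(1, "pfs_months", lower = 2, upper = 3)
  ev2 <- evaluate_criterion(c_band, list(orr_pct = 31))
  expect_true(is.na(ev2$satisfied))
  expect_equal(ev2$missing_metrics, "pfs_months")
  # a determinately false head makes the criterion false even with a
  # missing companion
  ev3 <- evaluate_criterion(c_comb, list(orr_pct = 80))
  expect_false(ev3$satisfied)
})

test_that("boundary values honor closed and open bounds", {
  cr <- grade_criterion(1, "hr_lower95", upper = 0.65, upper_closed = TRUE)
  expect_true(evaluate_criterion(cr, list(hr_lower95 = 0.65))$satisfied)
  cr_open <- grade_criterion(1, "pfs_months", lower = 2, upper = 3)
  expect_true(evaluate_criterion(cr_open, list(pfs_months = 2))$satisfied)
  expect_false(evaluate_criterion(cr_open, list(pfs_months = 3))$satisfied)
  # "not reached" satisfies any finite lower bound and fails a finite ceiling
  cr_dur <- grade_criterion(1, "docb_months", lower = 9)
  expect_true(evaluate_criterion(cr_dur, list(docb_months = Inf))$satisfied)
  cr_cap <- grade_criterion(1, "docb_months", upper = 6)
  expect_false(evaluate_criterion(cr_cap, list(docb_months = Inf))$satisfied)
})

test_that("preliminary grading distinguishes grade 0 from not assessable", {
  tb <- tables$neuro_mcbs_v1
  # all criteria determinately false: scored 0, not "not assessable"
  pg0 <- preliminary_grade(tb, list(pfs_months = 1, orr_pct = 5, dcr_pct = 8))
  expect_equal(pg0$grade, 0L)
  expect_true(pg0$assessable)
  # empty value map: everything indeterminate
  pg_na <- preliminary_grade(tb, list())
  expect_false(pg_na$assessable)
  # inputs from the basket-trial high-grade cohort (DCR/DoCB by proxy)
  pg3 <- preliminary_grade(tb, list(pfs_months = 4.5, orr_pct = 31,
                                    dcr_pct = 31, docb_months = 13.6))
  expect_equal(pg3$grade, 3L)
})

test_that("grade is order-invariant and extra criteria never lower it", {
  set.seed(401)
  for (rep in 1:50) {
    tb <- random_table()
    vals <- random_values()
    base <- preliminary_grade(tb, vals)$grade
    shuffled <- tb
    shuffled$criteria <- sample(tb$criteria)
    expect_identical(preliminary_grade(shuffled, vals)$grade, base)
    augmented <- tb
    augmented$criteria <- c(tb$criteria,
                            list(grade_criterion(1, "orr_pct", lower = 0)))
    aug <- preliminary_grade(augmented, vals)$grade
    if (!is.na(base) && !is.na(aug)) expect_gte(aug, base)
  }
})

test_that("an alternative registry file can be loaded", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(tables = list(list(
    table_id = "toy", max_preliminary = 1,
    criteria = list(list(grade = 1, metric = "orr_pct", lower = 50))))), path)
  reg <- mcbs_tables(path)
  expect_named(reg, "toy")
  expect_equal(preliminary_grade(reg$toy, list(orr_pct = 60))$grade, 1L)
})
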
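# neuromcbs

Rule-based grading of the **magnitude of clinical benefit** of neuro-oncology
therapies from structured study-outcome records.

Deciding whether a therapy for a CNS malignancy is "worth it" means weighing
survival and disease-control gains against treatment burden. The package
implements three instruments used for that judgment:

* **Neuro-MCBS** — a benefit scale for single-arm studies and individual
  (n-of-1) patients that credits durable disease control: grade 3 requires
  PFS ≥ 6 months, *or* ORR (CR+PR+MR) ≥ 60%, *or* DCR (CR+PR+MR+SD) ≥ 20 to
  < 60% with duration of clinical benefit ≥ 9 months; grades 2 and 1 lower
  these bands. A toxicity downgrade (−1 for ≥ 30% grade 3–4 toxicities) and a
  QoL/phase-4 upgrade (+1) adjust the preliminary grade, capped at 4.
* **ESMO-MCBS v1.1** — Forms 2a/2b (comparative trials, graded on the *lower
  95% CI limit* of the hazard ratio and the median gain, with bands split by
  the control-arm median), Form 2c (non-inferiority / other endpoints) and
  Form 3 (single-arm), with automatic form routing and the published
  assessability rules.
* **ASCO-NHB v2** — net health benefit = clinical-benefit points (from the HR
  *point estimate* or response-rate difference) + toxicity points + bonus
  points, capped at 130 (advanced) / 100 (adjuvant).

The scales are shipped as declarative, versioned grade tables
(`inst/extdata/grade_tables.yaml`, `asco_nhb_v2.yaml`) evaluated by one
generic highest-grade-fulfilled engine, so every score carries a full audit
trail: the criterion text that fired, the input values, any proxy
substitutions (ORR as a lower bound for missing DCR, DoR for missing DoCB),
and the band used.

## Worked example

Score the packaged single-arm study fixture with the Neuro-MCBS:

```r
library(neuromcbs)
t2 <- load_fixture("table2_single_arm")
scores <- score_records(t2, scale = "neuro")
scores_as_df(scores)[, c("record_id", "status", "preliminary", "final")]
#>         record_id         status preliminary final
#> 1        ROAR_HGG         scored           3     2
#> 2        ROAR_LGG         scored           3     3
#> 3  ALLIANCE071601         scored           3     2
#> 4 EVEROLIMUS_SEGA         scored           3     3
#> 5 SELUMETINIB_NF1         scored           3     4
#> 6         PBTC029 not_assessable          NA    NA
#> 7      ONC201_DMG         scored           3     3
```

Six of the seven scoring units receive a final score (4 = high-level clinical
benefit); PBTC029 reports neither PFS nor duration of response and is
truthfully not assessable. Printing a result shows its audit trail:

```r
print(scores[[1]])
#> <neuro_mcbs_v1 / neuro_mcbs> record ROAR_HGG
#>   preliminary 3, toxicity_downgrade (-1) -> final 2 (max 4)
#>   fired grade 3: DCR (CR + PR + MR + SD) >= 20 to < 60% and DoCB >= 9 months
#>   fired grade 2: PFS >= 3 to < 6 months
#>   note: proxy substitution: ORR used as lower bound for missing DCR; DoR (mean) used for missing DoCB
#>   note: policy: dcr_band_mode=as_printed
```

The preliminary 3 comes from disease control (ORR 31% standing in for DCR,
mean DoR 13.6 months for DoCB) and the grade 3–4 toxicity flag costs one
level. Comparative trials route automatically:

```r
t1 <- load_fixture("table1_comparative")
score_form2a(t1[[3]])  # OS gain 16.5 months, HR 0.6 (0.35-1.03) -> final 4
```

Cohort aggregation and the seeded synthetic n-of-1 generator:

```r
cohort <- generate_cohort(default_cohort_config(seed = 7))
summarize_cohort(score_cohort(cohort))   # per-entity % with score >= 3
```

See the vignette (`vignettes/clinical-benefit-scoring.Rmd`) for the scale
semantics, proxy policy, and the generator's assumptions.

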
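---
title: "Grading the clinical benefit of neuro-oncology therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading the clinical benefit of neuro-oncology therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromcbs)
```

## The problem

Whether a therapy is "worth it" for a patient with a CNS malignancy weighs the
expected gain in survival, disease control, and quality of life against
treatment burden. Two structured instruments dominate this assessment in
oncology: the ESMO Magnitude of Clinical Benefit Scale (ESMO-MCBS v1.1), a
graded scale with separate forms per trial design, and the ASCO Net Health
Benefit score (ASCO-NHB v2), a points framework. Neither credits durable
disease stabilization, which in neuro-oncology — where minor responses and
durable stable disease under RANO criteria are clinically meaningful — is
often the realistic best outcome. The Neuro-MCBS adapts the single-arm ESMO
form by grading on the disease control rate (DCR = CR + PR + MR + SD) and the
duration of clinical benefit (DoCB) alongside PFS and ORR.

This package implements all three instruments as a single rule engine over
*declarative grade tables*, scores structured study-outcome records (CSV or
JSON), and aggregates n-of-1 patient scores into per-entity benefit fractions.

## Scales as data, grading as one generic rule

Every scale row is an interval criterion: a head metric with an interval in
the printed ">= a to < b" convention (closed lower, open upper bound) plus
companion intervals that must hold jointly, e.g. grade 3 of the single-arm
scale:

> PFS >= 6 months, or ORR >= 60%, or DCR >= 20 to < 60% and DoCB >= 9 months.

The evaluator awards the **highest grade among satisfied criteria**. Three
result states are distinguished deliberately:

* **scored, grade >= 1** — some criterion fired;
* **scored, grade 0** ("no demonstrable benefit") — every criterion was
  determinate and none fired. The printed scale is labeled 1–4 and defines no
  row below PFS 2 months; the engine must still return something truthful
  there, and 0 is distinct from "not assessable";
* **not assessable** — every criterion was indeterminate (missing inputs), or
  the only criteria whose head interval held were blocked by an unreported
  duration (`duration_of_response_missing`). A criterion missing its head
  metric outright does *not* trigger the duration reason.

Tables live in `inst/extdata/grade_tables.yaml` with one source citation per
table, and are inspectable:

```{r}
mcbs_tables()$neuro_mcbs_v1
```

Keeping the ESMO v1.1 threshold transcriptions as versioned data rather than
code makes them auditable and replaceable: `mcbs_tables(path)` loads an
alternative registry.

## Parameters that matter

* **Hazard-ratio limit.** The comparative ESMO forms grade on the *lower
  limit of the 95% CI* of the hazard ratio, never the point estimate; the
  ASCO framework uses the *point estimate*. The `hr_estimate` container
  carries both so neither engine can grab the wrong number.
* **Band selection (Form 2a/2b).** Form 2a's thresholds differ by control-arm
  median OS (cut at 12 months; Form 2b cuts at median PFS 6 months). Trial
  tables often omit control medians, so the engine evaluates both bands when
  the median is missing: an identical grade is reported as `band_invariant`;
  differing grades yield `not_assessable(control_median_required)` rather
  than a guess.
* **Ternary flags.** Toxicity/QoL flags are `yes`/`no`/`unknown`, not
  booleans, because published tables distinguish "no" from "not reported".
  `unknown` blocks an upgrade but never triggers a downgrade.
* **Proxy policy.** Single-arm tables usually report ORR and DoR, not DCR and
  DoCB. Since responders are a subset of disease control, ORR is a certified
  lower bound of DCR, and substituting it can only under-grade. By default
  `proxy_policy()` allows ORR-for-DCR and DoR-for-DoCB; every substitution is
  recorded in the audit trail, and both proxies can be disabled.
* **Durations** are months everywhere after loading (`normalize_duration()`
  converts gains printed in years); "not reached" is a distinct file token
  stored as `Inf`, which satisfies any finite lower bound.
* **Benefit threshold.** Cohort summaries count final scores >= 3 as net
  clinical benefit by default (configurable). Percentages round half-up,
  which is the convention that reproduces published cohort percentages
  (5/8 prints as 63%, not 62%).

## Numerical and design choices

* **DCR band ceilings.** Read literally, "DCR >= 20 to < 60%" means a study
  with DCR 70% and long DoCB satisfies no grade-3 row unless ORR >= 60 — a
  non-monotonicity in the printed scale. The default `dcr_band_mode =
  "as_printed"` implements the literal bands and warns when a value
  overshoots every band ceiling without a higher-grade path;
  `"monotone"` drops the DCR upper bounds. Fidelity first: the anomaly is
  surfaced, not silently repaired.
* **Downgrade below 1.** The printed scale does not say whether a toxicity
  downgrade can take a preliminary 1 to 0; the engine allows it (floor 0) and
  the audit trail makes the path visible.
* **Single upgrade.** QoL improvement and phase-4 confirmation together still
  add only +1 ("upgrade 1 level if ... or ...").
* **n-of-1 convention.** A patient's best response becomes a degenerate rate
  (ORR/DCR of 0 or 100) and their own PFS/DoCB are the durations. DoCB is
  never imputed from PFS for stable disease; an explicit value is required.
* **Form 2c.** Only the non-inferiority gate is printed in the source tables
  this package reproduces: non-inferiority met *and* positive toxicity/QoL
  evidence scores the form's maximum of 4; unreported evidence is
  `insufficient_toxicity_data`; explicit negative evidence scores 0. The
  other-endpoint superiority path uses a conservative preliminary 2 with the
  usual +1 upgrade, and is exercised by property tests only.
* **Form 2b sub-grade thresholds.** Only the grade-3 cut-offs of Form 2b are
  pinned by a reproducible published score; the grade-2/1 rows in the
  registry follow the cited v1.1 publication but no fixture exercises them.
* **ASCO-NHB v2.** Clinical benefit is `(1 - HR) x 100` (OS basis; x 80 for
  PFS, x 0.7 per percentage point of response-rate difference), capped at 80;
  toxicity points scale the relative grade 3–4 rate difference to ±20;
  advanced-setting bonuses (tail of curve 20, palliation 10, QoL 10,
  treatment-free interval 10) never apply in the adjuvant setting; caps are
  130/100 and a binding cap is itself an audit component so the decomposition
  always sums to the reported NHB. Published NHB values depend on
  original-trial toxicity tables that are not part of the record format, so
  this module is validated by properties (caps, monotonicity in HR, exact
  decomposition), not by reproducing printed numbers.

## What the synthetic generator does and does not show

`generate_cohort()` emulates the *structure* of a molecular-tumor-board
cohort: 70 patients split 8 meningioma / 10 brain metastases / 36
glioblastoma / 8 IDH-mutant astrocytoma / 8 other, therapy classes weighted
by the published tabulation, exponential PFS per entity (medians 8, 7, 2.5,
3.5 and 4 months — plausible for heavily pretreated CNS cohorts), categorical
best response per entity, log-normal DoCB truncated at the patient's PFS, and
Bernoulli toxicity (rate 0.15) and QoL-improvement (rate 0.05) flags. These
defaults were fixed once as the simulated study conditions.

It does **not** model correlation between response depth and PFS, censoring,
response assessment error, or per-therapy effects. Passing tests on
simulated cohorts therefore demonstrate that the engine implements the scale
faithfully (scores match a straight-line re-implementation patient by
patient; mean score responds to median PFS; generation is deterministic per
seed), not that the scale is clinically valid on real patients.

Test problem sizes: the evaluator-vs-oracle property runs 1,000 random
tables; monotonicity sweeps and score-bound checks use a few hundred random
records; the cohort-response check scores two cohorts of 10,000 simulated
patients.

## Worked example

```{r}
t2 <- load_fixture("table2_single_arm")
scores <- score_records(t2, scale = "neuro")
scores_as_df(scores)[, c("record_id", "status", "preliminary", "final")]
```

Six of the seven single-arm scoring units score (one lacks both PFS and
duration of response and is truthfully not assessable), and the audit trail
for any unit shows exactly which criterion fired:

```{r}
print(scores[[1]])
```

## Known limitations

* ESMO v1.1 Forms 2a/2b threshold tables are transcriptions from the cited
  publications, validated against every reproducible published score; rows
  of the forms never exercised by those scores carry transcription risk.
* The engine consumes already-categorized responses; it performs no RANO
  measurement, no survival analysis, and no study selection.
* Records are trusted after schema validation; the engine does not detect
  clinically implausible inputs beyond the type invariants.
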
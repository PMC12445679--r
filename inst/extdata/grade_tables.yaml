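# Grade-table registry: declarative scale definitions evaluated by the generic
# highest-grade-fulfilled engine. Rates are percentages (0-100), durations are
# months, hr_lower95 is the lower limit of the 95% CI of the hazard ratio.
# Interval convention: ">= a to < b" = closed lower bound, open upper bound.
tables:

  - table_id: neuro_mcbs_v1
    max_preliminary: 3
    source: >-
      Neuro-Oncology Magnitude of Clinical Benefit Scale for single-arm
      studies, Step 1 grade criteria (single-arm modification of ESMO-MCBS
      v1.1 Form 3 crediting disease control: DCR = CR+PR+MR+SD, DoCB =
      duration of clinical benefit).
    criteria:
      - {grade: 3, metric: pfs_months, lower: 6,
         label: "PFS >= 6 months"}
      - {grade: 3, metric: orr_pct, lower: 60,
         label: "ORR (CR + PR + MR) >= 60%"}
      - {grade: 3, metric: dcr_pct, lower: 20, upper: 60,
         companions: [{metric: docb_months, lower: 9}],
         label: "DCR (CR + PR + MR + SD) >= 20 to < 60% and DoCB >= 9 months"}
      - {grade: 2, metric: pfs_months, lower: 3, upper: 6,
         label: "PFS >= 3 to < 6 months"}
      - {grade: 2, metric: orr_pct, lower: 40, upper: 60,
         label: "ORR (CR + PR + MR) >= 40 to < 60%"}
      - {grade: 2, metric: dcr_pct, lower: 20, upper: 40,
         companions: [{metric: docb_months, lower: 6, upper: 9}],
         label: "DCR (CR + PR + MR + SD) >= 20 to < 40% and DoCB >= 6 to < 9 months"}
      - {grade: 1, metric: pfs_months, lower: 2, upper: 3,
         label: "PFS >= 2 to < 3 months"}
      - {grade: 1, metric: orr_pct, lower: 20, upper: 40,
         companions: [{metric: docb_months, upper: 6}],
         label: "ORR (CR + PR + MR) >= 20 to < 40% and DoCB < 6 months"}
      - {grade: 1, metric: dcr_pct, lower: 10, upper: 20,
         companions: [{metric: docb_months, lower: 6}],
         label: "DCR (CR + PR + MR + SD) >= 10 to < 20% and DoCB >= 6 months"}

  - table_id: esmo_form3_v1_1
    max_preliminary: 3
    source: >-
      ESMO-MCBS v1.1 Form 3 (single-arm studies in orphan diseases or areas of
      high unmet need), transcribed from Cherny et al., ESMO-Magnitude of
      Clinical Benefit Scale version 1.1, Ann Oncol 2017;28:2340-2366.
    criteria:
      - {grade: 3, metric: pfs_months, lower: 6,
         label: "PFS >= 6 months"}
      - {grade: 3, metric: orr_pct, lower: 60,
         label: "ORR >= 60%"}
      - {grade: 3, metric: orr_pct, lower: 20, upper: 60,
         companions: [{metric: dor_months, lower: 9}],
         label: "ORR >= 20 to < 60% and DoR >= 9 months"}
      - {grade: 2, metric: pfs_months, lower: 3, upper: 6,
         label: "PFS >= 3 to < 6 months"}
      - {grade: 2, metric: orr_pct, lower: 40, upper: 60,
         label: "ORR >= 40 to < 60%"}
      - {grade: 2, metric: orr_pct, lower: 20, upper: 40,
         companions: [{metric: dor_months, lower: 6, upper: 9}],
         label: "ORR >= 20 to < 40% and DoR >= 6 to < 9 months"}
      - {grade: 1, metric: pfs_months, lower: 2, upper: 3,
         label: "PFS >= 2 to < 3 months"}
      - {grade: 1, metric: orr_pct, lower: 20, upper: 40,
         companions: [{metric: dor_months, upper: 6}],
         label: "ORR >= 20 to < 40% and DoR < 6 months"}
      - {grade: 1, metric: orr_pct, lower: 10, upper: 20,
         companions: [{metric: dor_months, lower: 6}],
         label: "ORR >= 10 to < 20% and DoR >= 6 months"}

  # Form 2a: comparative trials with OS primary endpoint; grading on the lower
  # limit of the 95% CI of the OS hazard ratio and the median OS gain. Two
  # bands split at a control-arm median OS of 12 months. Landmark-survival
  # criteria are consulted only when the median gain is not reported.
  - table_id: esmo_form2a_le12_v1_1
    max_preliminary: 4
    source: >-
      ESMO-MCBS v1.1 Form 2a, band for control-arm median OS <= 12 months;
      transcribed from Cherny et al., Ann Oncol 2017;28:2340-2366.
    criteria:
      - {grade: 4, metric: hr_lower95, upper: 0.65, upper_closed: true,
         companions: [{metric: gain_months, lower: 3}],
         label: "HR LL95%CI <= 0.65 and OS gain >= 3 months"}
      - {grade: 4, metric: landmark_gain_pct, lower: 10,
         companions: [{metric: landmark_years, lower: 2, upper: 2, upper_closed: true}],
         label: "gain in 2-year survival alone >= 10%"}
      - {grade: 3, metric: hr_lower95, upper: 0.65, upper_closed: true,
         companions: [{metric: gain_months, lower: 2.5}],
         label: "HR LL95%CI <= 0.65 and OS gain >= 2.5 months"}
      - {grade: 2, metric: hr_lower95, upper: 0.70, upper_closed: true,
         companions: [{metric: gain_months, lower: 1.5}],
         label: "HR LL95%CI <= 0.70 and OS gain >= 1.5 months"}
      - {grade: 1, metric: hr_lower95, lower: 0,
         label: "statistically significant OS benefit below grade-2 thresholds"}

  - table_id: esmo_form2a_gt12_v1_1
    max_preliminary: 4
    source: >-
      ESMO-MCBS v1.1 Form 2a, band for control-arm median OS > 12 months;
      transcribed from Cherny et al., Ann Oncol 2017;28:2340-2366.
    criteria:
      - {grade: 4, metric: hr_lower95, upper: 0.70, upper_closed: true,
         companions: [{metric: gain_months, lower: 5}],
         label: "HR LL95%CI <= 0.70 and OS gain >= 5 months"}
      - {grade: 4, metric: landmark_gain_pct, lower: 10,
         companions: [{metric: landmark_years, lower: 3, upper: 3, upper_closed: true}],
         label: "gain in 3-year survival alone >= 10%"}
      - {grade: 3, metric: hr_lower95, upper: 0.70, upper_closed: true,
         companions: [{metric: gain_months, lower: 3}],
         label: "HR LL95%CI <= 0.70 and OS gain >= 3 months"}
      - {grade: 2, metric: hr_lower95, upper: 0.75, upper_closed: true,
         companions: [{metric: gain_months, lower: 1.5}],
         label: "HR LL95%CI <= 0.75 and OS gain >= 1.5 months"}
      - {grade: 1, metric: hr_lower95, lower: 0,
         label: "statistically significant OS benefit below grade-2 thresholds"}

  # Form 2b: comparative trials with PFS primary endpoint (records with a
  # demonstrated OS benefit are routed to Form 2a instead). Bands split at a
  # control-arm median PFS of 6 months. Preliminary maximum 3; adjustments can
  # raise the final score to 4.
  - table_id: esmo_form2b_le6_v1_1
    max_preliminary: 3
    source: >-
      ESMO-MCBS v1.1 Form 2b, band for control-arm median PFS <= 6 months;
      transcribed from Cherny et al., Ann Oncol 2017;28:2340-2366.
    criteria:
      - {grade: 3, metric: hr_lower95, upper: 0.65, upper_closed: true,
         companions: [{metric: gain_months, lower: 1.5}],
         label: "HR LL95%CI <= 0.65 and PFS gain >= 1.5 months"}
      - {grade: 2, metric: hr_lower95, upper: 0.75, upper_closed: true,
         companions: [{metric: gain_months, lower: 1.5}],
         label: "HR LL95%CI <= 0.75 and PFS gain >= 1.5 months"}
      - {grade: 1, metric: hr_lower95, lower: 0,
         label: "statistically significant PFS benefit below grade-2 thresholds"}

  - table_id: esmo_form2b_gt6_v1_1
    max_preliminary: 3
    source: >-
      ESMO-MCBS v1.1 Form 2b, band for control-arm median PFS > 6 months;
      transcribed from Cherny et al., Ann Oncol 2017;28:2340-2366.
    criteria:
      - {grade: 3, metric: hr_lower95, upper: 0.65, upper_closed: true,
         companions: [{metric: gain_months, lower: 3}],
         label: "HR LL95%CI <= 0.65 and PFS gain >= 3 months"}
      - {grade: 2, metric: hr_lower95, upper: 0.75, upper_closed: true,
         companions: [{metric: gain_months, lower: 1.5}],
         label: "HR LL95%CI <= 0.75 and PFS gain >= 1.5 months"}
      - {grade: 1, metric: hr_lower95, lower: 0,
         label: "statistically significant PFS benefit below grade-2 thresholds"}
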
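# ASCO Net Health Benefit v2 point schedule, transcribed from Schnipper et
# al., Updating the American Society of Clinical Oncology Value Framework,
# J Clin Oncol 2016;34:2925-2934. Clinical benefit uses the hazard-ratio POINT
# estimate (unlike the ESMO forms, which use the lower 95% CI limit).
version: asco_nhb_v2
clinical_benefit:
  max_points: 80
  # points = (1 - HR) * multiplier for hazard-ratio bases;
  # points = rr_diff_pct * (multiplier / 100) for the response-rate basis
  multiplier:
    os_hr: 100
    pfs_hr: 80
    rr: 70
toxicity:
  # points = scale * (control_rate - treatment_rate) / max(rates), in
  # [-max_points, +max_points]
  max_points: 20
bonus:   # advanced setting only
  tail_of_curve: 20
  palliation: 10
  qol_improved: 10
  treatment_free_interval: 10
caps:
  advanced: 130
  adjuvant: 100
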
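record_id,study,design,primary_endpoint,n_subjects,superiority_met,noninferiority_met,os_gain,os_gain_unit,os_control_median_months,os_hr,os_landmark_gain_pct,os_landmark_years,pfs_gain,pfs_gain_unit,pfs_control_median_months,pfs_hr,single_arm_pfs_months,orr_pct,dcr_pct,dor_months,dor_statistic,docb_months,response_criteria,best_response,toxicity_ge30pct_grade34,toxicity_reduced_vs_control,qol_assessed,qol_improved,phase4_confirmation,crossover_penalty,subgroup_label,entity,therapy_class,note,control_median_external,expected_form,expected_esmo,expected_asco
EORTC26981,EORTC 26981-22981/NCIC CE3,comparative_superiority,OS,573,yes,unknown,2.5,months,12.1,0·63 (0·53–0·75),,,1.9,months,,0.63 (0.53-0.75),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,,glioblastoma,,RT+TMZ vs. RT alone,yes,form2a,2,34.8
EF14,EF-14,comparative_superiority,PFS,695,yes,unknown,4.9,months,16.0,0.63 (0.53-0.76),,,2.7,months,,0.63 (0.52-0.76),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,,glioblastoma,,RT+TMZ+TTF vs. RT+TMZ; routed to Form 2a because OS benefit demonstrated,yes,form2a,3,26
CETEG,CeTeG/NOA-09,comparative_superiority,OS,144,yes,unknown,16.5,months,,0.6 (0.35-1.03),,,(-),,,0.99 (0·68–1·46),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,MGMT methylated,glioblastoma,,RT+TMZ+CCNU vs. RT+TMZ,no,form2a,4,37.75
NOA08,NOA-08,comparative_noninferiority,OS,373,unknown,yes,-1,months,,1.09 (0.84-1.42),,,-1.4,months,,1.15 (0.92-1.43),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,,anaplastic astrocytoma/glioblastoma elderly,,gains printed as (-1 month) and (-1.4 months); toxicity reporting insufficient for Form 2c,no,form2c,n/a:insufficient_toxicity_data,n/a:noninferiority_design_unsupported
NORDIC_HFRT,Nordic Trial,comparative_superiority,OS,98,no,unknown,1.5,months,,0.85 (0.64-1.12),,,(-),,,(-),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,HFRT arm,glioblastoma elderly,,HFRT vs. RT arm did not reach statistical significance,no,form2a,n/a:no_statistical_significance,n/a:no_statistical_significance
NORDIC_TMZ,Nordic Trial,comparative_superiority,OS,93,yes,unknown,2.3,months,,0.70 (0.52-0.93),,,(-),,,(-),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,TMZ arm,glioblastoma elderly,,TMZ vs. RT arm,no,form2a,2,17.1
PERRY,Short-course radiation plus Temozolomide in the elderly,comparative_superiority,OS,562,yes,unknown,1.7,months,,0.67 (0.56-0.80),,,1.4,months,,0.50 (0.41-0.60),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,,glioblastoma elderly,,mPFS gain printed as bare 1.4 without a unit; stored as months per the column convention,no,form2a,2,33
RTOG9402_OVERALL,RTOG9402,comparative_superiority,OS,291,no,unknown,-0.1,years,,0.79 (0.60-1.04),,,(-),,,(-),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,,anaplastic oligodendroglioma,,PCV->RT vs. RT; gain printed as (-0.1 years); overall comparison not significant,no,form2a,n/a:no_statistical_significance,n/a:no_statistical_significance
RTOG9402_IDHMUT,RTOG9402,comparative_superiority,OS,156,yes,unknown,3.7,years,,0.59 (0.40-0.86),,,(-),,,(-),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,IDH mutant,anaplastic oligodendroglioma,,post hoc molecular subgroup,no,form2a,4,33.2
RTOG9402_CODEL,RTOG9402,comparative_superiority,OS,10,yes,unknown,7.3,years,,0.59 (0.37-0.95),,,(-),,,(-),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,1p19q co-del,anaplastic oligodendroglioma,,printed n = 10 reproduced without correction despite apparent inconsistency with other subgroup sizes,no,form2a,4,33.2
RTOG9402_IDHMUT_CODEL,RTOG9402,comparative_superiority,OS,88,yes,unknown,7.9,years,,0.49 (0.28-0.85),,,(-),,,(-),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,IDH mutant and 1p19q co-del,anaplastic oligodendroglioma,,post hoc molecular subgroup,no,form2a,4,43.2
RTOG9402_IDHMUT_NOCODEL,RTOG9402,comparative_superiority,OS,66,yes,unknown,2.2,years,,0.56 (0.32-0.99),,,(-),,,(-),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,"IDH mutant, not 1p19q co-del",anaplastic oligodendroglioma,,post hoc molecular subgroup,no,form2a,4,36.2
EORTC26951,EORTC 26951,comparative_superiority,OS,368,yes,unknown,11.7,months,,0.75 (0.60-0.95),,,11.1,months,,0.66 (0.52-0.83),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,,anaplastic oligodendroglioma,,RT->PCV vs. RT; limited report of toxicity data,no,form2a,4,45
RTOG9802,RTOG 9802,comparative_superiority,OS,251,yes,unknown,5.5,years,,0.59 (0.42-0.83),,,6.4,years,,0.5 (0.36-0.68),,,,,,,,,unknown,unknown,unknown,unknown,unknown,unknown,,low-grade glioma,,RT->PCV vs. RT; gains printed in years,no,form2a,4,11
INDIGO,INDIGO,comparative_superiority,PFS,331,yes,unknown,(-),,,(-),,,16.6,months,,0.39 (0.27-0.56),,,,,,,,,unknown,unknown,yes,yes,unknown,unknown,,low-grade glioma,,Vorasidenib vs. placebo; printed final 4 requires an adjustment credit - encoded as a QoL upgrade (editorial assumption),no,form2b,4,79.5
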
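record_id,study,design,primary_endpoint,n_subjects,superiority_met,noninferiority_met,os_gain,os_gain_unit,os_control_median_months,os_hr,os_landmark_gain_pct,os_landmark_years,pfs_gain,pfs_gain_unit,pfs_control_median_months,pfs_hr,single_arm_pfs_months,orr_pct,dcr_pct,dor_months,dor_statistic,docb_months,response_criteria,best_response,toxicity_ge30pct_grade34,toxicity_reduced_vs_control,qol_assessed,qol_improved,phase4_confirmation,crossover_penalty,subgroup_label,entity,therapy_class,note,expected_esmo,expected_neuro
ROAR_HGG,ROAR,single_arm,ORR,45,unknown,unknown,,,,,,,,,,,4.5,31,,13.6,mean,,RANO (PR+CR+MR),,yes,unknown,unknown,unknown,unknown,unknown,High-grade glioma cohort,BRAFV600E mutant high-grade glioma,TK inhibition,basket-trial cohort scored as a separate single-arm study; mOS 17.6 months; QoL studies not reported,2,2
ROAR_LGG,ROAR,single_arm,ORR,13,unknown,unknown,,,,,,,,,,,14.0,69,,27.5,mean,,RANO (PR+CR+MR),,no,unknown,unknown,unknown,unknown,unknown,Low-grade glioma cohort,BRAFV600E mutant low-grade glioma,TK inhibition,basket-trial cohort scored as a separate single-arm study; mOS not reached; QoL studies not reported,3,3
ALLIANCE071601,Alliance 071601,single_arm,ORR,16,unknown,unknown,,,,,,,,,,,,94,,,unspecified,,ORR (CR+PR),,yes,unknown,unknown,unknown,unknown,unknown,,papillary craniopharyngioma,TK inhibition,QoL studies not reported,2,2
EVEROLIMUS_SEGA,NCT00411619/EXIST-1,single_arm,safety,28,unknown,unknown,,,,,,,,,,,,75,,,unspecified,,change in tumor volume within 6 months,,yes,unknown,yes,yes,unknown,unknown,,subependymal giant-cell astrocytoma,mTOR inhibition,,3,3
SELUMETINIB_NF1,NCT01362803,single_arm,ORR,50,unknown,unknown,,,,,,,,,,,,68,,not reached,mean,,volumetric MRI,,no,unknown,yes,yes,unknown,unknown,,plexiform neurofibroma in NF1,TK inhibition,,4,4
PBTC029,PBTC-029,single_arm,ORR,25,unknown,unknown,,,,,,,,,,,,24,,,unspecified,,ORR (CR+PR) sustained >= 8 weeks,,no,unknown,unknown,unknown,unknown,unknown,,sporadic optic pathway/hypothalamic low-grade glioma,TK inhibition,DoR not reported; n = 2 with MR; QoL studies not reported,n/a:duration_of_response_missing,n/a:duration_of_response_missing
ONC201_DMG,Arrillaga-Romany et al.,single_arm,ORR,50,unknown,unknown,,,,,,,,,,,,20,,11.2,mean,,RANO (CR+PR),,no,unknown,unknown,unknown,unknown,unknown,,H3K27M mutant diffuse midline glioma,other,pooled efficacy analysis of single-arm studies; mOS 13.7 months; QoL studies not reported,3,3
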
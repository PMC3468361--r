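patient,primary_tumour,reference_site,baseline_perfusion_ml_min_g,perfusion_change_pct,baseline_fdg_suv,suv_change_wk2_pct,suv_change_wk4_pct,fdg_response,ref_lesion_recist,overall_recist,duration_cycles,clinical_benefit,trough_ng_ml,vegf_d15_d1,svegfr2_d15_d1
1,Renal,Right hepatic lobe,0.81,-85,4.6,-39,-48,Yes,SD,SD,4,Yes,76.4,5.29,0.66
2,Colon,Right hepatic lesion,1.18,-77,6.5,-37,-59,Yes,SD,SD,6,Yes,134.9,4.85,0.44
3,Colon,Right hepatic lobe,1.52,-59,4.2,-33,-29,Yes,PD,PD,2,No,90.8,8.67,0.34
4,Colon,Right hepatic lobe,1.28,-34,9.8,-44,-13,Yes,PD,PD,2,No,27.6,2.56,0.75
5,NSCLC,Left lung lesion,0.74,-69,12.3,-67,-66,Yes,SD,SD,12,Yes,107.1,4.17,0.49
6,Colon,Right hepatic lesion,1.39,-38,6.0,-32,-18,Yes,SD,SD,7,Yes,88.8,NA,NA
7,Oesophageal,Right hepatic dome,1.23,-20,4.1,-29,-41,No,PD,PD,2,No,105.0,NA,NA
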
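# Published survey of maximum organ doses from MVCT delivery at normal pitch
# on a helical tomotherapy unit (five clinical sites, 21 organs). Columns:
# prescription fraction dose (cGy) and fraction count, maximum organ dose per
# imaging fraction (cGy), total maximum dose over the course (cGy), and the
# total as a percentage of the prescribed dose. Totals were computed by the
# source from unrounded per-fraction values, so rows other than "Brain" are
# not exactly reproducible from the rounded max_per_fx_cGy column.
region,organ,fraction_dose_cGy,n_fractions,max_per_fx_cGy,total_max_cGy,percent_of_prescription
Brain,Brain,300,10,1.88,18.80,0.63
Brain,Brain stem,300,10,1.66,16.57,0.55
Brain,R-eye,300,10,1.77,17.67,0.59
Brain,L-eye,300,10,1.84,18.40,0.61
Head and neck,L-parotid,180,39,1.62,63.14,0.90
Head and neck,R-parotid,180,39,1.92,74.72,1.06
Head and neck,Oral cavity,180,39,1.86,72.35,1.03
Head and neck,Spinal cord,180,39,1.73,67.51,0.96
Lung,L-lung,180,33,1.68,55.34,0.93
Lung,R-lung,180,33,1.55,51.18,0.86
Lung,Spinal cord,180,33,1.51,49.96,0.84
Lung,Heart,180,33,1.63,53.79,0.91
Abdomen,Stomach,180,28,1.70,47.60,0.94
Abdomen,R-kidney,180,28,1.65,46.20,0.92
Abdomen,L-kidney,180,28,1.59,44.38,0.88
Abdomen,Spinal cord,180,28,1.53,42.92,0.85
Abdomen,Duodenum,180,28,1.60,44.88,0.89
Prostate,Bladder,200,38,1.24,47.27,0.62
Prostate,FHs,200,38,1.53,58.22,0.77
Prostate,Rectum,200,38,1.44,54.68,0.72
Prostate,Prostate,200,38,1.31,49.82,0.66
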
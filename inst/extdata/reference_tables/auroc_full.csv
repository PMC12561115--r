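task,dataset,wd_auroc,wd_sd,mse_auroc,mse_sd
failure_detection,Brain,0.66,0.03,0.20,0.02
failure_detection,Cervix,0.71,0.02,0.48,0.02
failure_detection,Head and Neck,0.37,0.02,0.15,0.01
failure_detection,Lung,0.89,0.01,0.79,0.01
failure_detection,Needles,0.69,0.02,0.58,0.03
failure_detection,Ascites,0.60,0.02,0.43,0.03
data_curation,Bone Suppression,0.68,0.02,0.79,0.01
data_curation,Filtered,0.57,0.02,0.98,0.00
data_curation,Missing Lung,0.58,0.02,0.82,0.01
data_curation,Inverted,0.84,0.01,0.90,0.01
data_curation,No Anatomy,0.63,0.04,0.62,0.01
data_curation,Orientation,0.74,0.05,0.78,0.03
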
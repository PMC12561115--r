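dataset,wd_auroc,wd_sd,mse_auroc,mse_sd
Brain,1.00,0.00,0.90,0.01
Cervix,0.90,0.01,0.70,0.02
Head and Neck,0.96,0.00,0.90,0.01
Lung,0.94,0.01,0.90,0.01
Needles,0.69,0.02,0.60,0.02
Ascites,0.67,0.02,0.50,0.03
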
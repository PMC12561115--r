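dataset,metric,baseline_fd,baseline_sd,generated_fd,generated_sd,noise_fd,noise_sd,blur_fd,blur_sd
liver_ct,FID,0.26,0.00,3.37,0.05,31.43,0.17,47.65,0.13
liver_ct,FSD,0.01,0.00,0.96,0.00,4.45,0.01,0.44,0.00
liver_ct,FRD,0.01,0.00,0.81,0.04,216.28,0.34,164.54,0.60
chest_radiography,FID,0.40,0.00,4.49,0.03,86.65,0.19,36.98,0.12
chest_radiography,FSD,0.02,0.00,0.92,0.00,14.90,0.01,1.41,0.01
chest_radiography,FRD,0.02,0.01,8.56,0.03,403.29,10.57,49.64,5.30
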
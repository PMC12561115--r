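dataset,metric,d,proportion,sd
Needles,wd,32,0.43,0.01
Needles,wd,64,0.41,0.02
Needles,wd,128,0.70,0.03
Needles,mse,32,0.44,0.01
Needles,mse,64,0.38,0.03
Needles,mse,128,0.35,0.03
Ascites,wd,32,0.55,0.06
Ascites,wd,64,0.71,0.03
Ascites,wd,128,0.93,0.01
Ascites,mse,32,0.44,0.05
Ascites,mse,64,0.66,0.04
Ascites,mse,128,0.86,0.02
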
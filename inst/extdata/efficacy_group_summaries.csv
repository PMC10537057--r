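group,endpoint,mean,sd,reported_percent_change
normal_control,protein,5.05,0.40,NA
LIU,clinical_score,3.732,0.053,100
LIU,protein,45.61,1.63,801.47
DEX-AqS,clinical_score,2.670,0.085,28.45
DEX-AqS,protein,28.08,1.09,38.4
DEX-CSNPs,clinical_score,1.578,0.048,57.71
DEX-CSNPs,protein,21.48,0.66,52.9
HA-DEX-CSNPs,clinical_score,0.930,0.053,75.08
HA-DEX-CSNPs,protein,16.27,0.46,64.3
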
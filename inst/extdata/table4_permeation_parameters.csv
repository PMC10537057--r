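formulation,parameter,mean,sd
DEX-AqS,q_0_5h_ug_per_cm2,58.44,3.04
DEX-AqS,q_6h_ug_per_cm2,66.86,3.51
DEX-AqS,flux_j_ug_per_cm2_per_h,1.76,0.13
DEX-AqS,p_app_cm_per_h_e3,3.52,0.25
DEX-CSNPs,q_0_5h_ug_per_cm2,28.36,2.05
DEX-CSNPs,q_6h_ug_per_cm2,59.52,3.67
DEX-CSNPs,flux_j_ug_per_cm2_per_h,8.27,0.49
DEX-CSNPs,enhancement_ratio,4.70,0.39
DEX-CSNPs,p_app_cm_per_h_e3,16.53,0.99
HA-DEX-CSNPs,q_0_5h_ug_per_cm2,11.86,3.12
HA-DEX-CSNPs,q_6h_ug_per_cm2,69.32,4.58
HA-DEX-CSNPs,flux_j_ug_per_cm2_per_h,17.81,0.43
HA-DEX-CSNPs,enhancement_ratio,10.14,0.92
HA-DEX-CSNPs,p_app_cm_per_h_e3,35.62,0.86
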
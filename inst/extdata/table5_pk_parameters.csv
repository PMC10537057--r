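formulation,parameter,mean,sd
DEX-AqS,t_half_h,2.18,0.37
DEX-AqS,t_max_h,4.00,0.00
DEX-AqS,c_max_ng_per_ml,809.26,45.51
DEX-AqS,auc_0_24_ng_h_per_ml,2826.71,219.84
DEX-AqS,auc_0_inf_ng_h_per_ml,2830.95,224.12
DEX-AqS,auc_ratio,0.99,0.001
DEX-AqS,aumc_0_inf_ng_h2_per_ml,11458.50,1239.01
DEX-AqS,mrt_0_inf_h,4.04,0.12
DEX-CSNPs,t_half_h,5.44,0.70
DEX-CSNPs,t_max_h,6.00,0.00
DEX-CSNPs,c_max_ng_per_ml,561.79,40.51
DEX-CSNPs,auc_0_24_ng_h_per_ml,5294.19,687.36
DEX-CSNPs,auc_0_inf_ng_h_per_ml,5727.33,897.67
DEX-CSNPs,auc_ratio,0.93,0.02
DEX-CSNPs,aumc_0_inf_ng_h2_per_ml,57896.82,14377.82
DEX-CSNPs,mrt_0_inf_h,10.01,0.89
HA-DEX-CSNPs,t_half_h,7.34,1.22
HA-DEX-CSNPs,t_max_h,6.00,0.00
HA-DEX-CSNPs,c_max_ng_per_ml,584.32,50.74
HA-DEX-CSNPs,auc_0_24_ng_h_per_ml,6691.48,570.10
HA-DEX-CSNPs,auc_0_inf_ng_h_per_ml,7774.81,489.53
HA-DEX-CSNPs,auc_ratio,0.86,0.04
HA-DEX-CSNPs,aumc_0_inf_ng_h2_per_ml,99040.13,15826.01
HA-DEX-CSNPs,mrt_0_inf_h,12.73,1.77
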
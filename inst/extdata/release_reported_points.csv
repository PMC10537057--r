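formulation,time_h,percent_released
DEX-CSNPs,1,33.62
DEX-CSNPs,3,56.32
DEX-CSNPs,12,74.2
HA-DEX-CSNPs,1,13.49
HA-DEX-CSNPs,3,31.54
HA-DEX-CSNPs,12,77.1
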
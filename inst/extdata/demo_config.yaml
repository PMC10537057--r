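# All-synthetic demo run: simulate every experiment, analyse, and report.
seed: 1
outdir: ocukin-demo
stages: [simulate, release, permeation, nca, efficacy, report]
constants:
  medium_volume: 50     # mL simulated tear fluid
  dose: 1000            # ug drug in the dialysis bag
  sample_volume: 1      # mL withdrawn and replaced per sample
  c0: 500               # ug/mL donor concentration
  area: 0.636           # cm^2 corneal cross-section
  receptor_volume: 6.9  # mL receptor compartment
options:
  estimator: corrected
  trapezoid: linear
  reference_formulation: DEX-AqS
  reference_group_reduction: LIU
  reference_group_increase: normal_control
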
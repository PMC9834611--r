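species_name: mouse
body_weight: 0.025
hematocrit: 0.45
cardiac_output: ~
co_coefficient: 16.5
co_exponent: 0.75
tissue_weight_fraction:
  brain: 1.65
  bone_marrow: 3.1
  kidney: 1.67
  liver: 5.49
  gut: 4.22
  slowly_perfused: 70.5
  rapidly_perfused: 8.43
  blood: 4.9
tissue_flow_fraction:
  brain: 3.3
  bone_marrow: 1.0
  kidney: 9.1
  liver: 2.0
  gut: 13.0
  slowly_perfused: 35.0
  rapidly_perfused: 36.6
brain_tissue_fraction: 0.97
brain_blood_fraction: 0.03
lung_weight_fraction: 0.75
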
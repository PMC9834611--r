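molecular_weight_g_mol: 811.0
KD_tubulin_nM: 196.08
BC_nmol_kg:
  brain: 10710.0
  lung: 2580.0
  bone_marrow: 371.25
  kidney: 1470.0
  liver: 3510.0
  gut: 1080.0
  slowly_perfused: 900.0
  rapidly_perfused: 3420.0
  blood: 0.0
PC:
  brain: 1.21
  lung: 1.0
  bone_marrow: 1.0
  kidney: 3.73
  liver: 2.26
  gut: 1.08
  slowly_perfused: 1.0
  rapidly_perfused: 1.0
  blood: 1.0
SF_ABCB1:
  brain: 1.0
  gut: 0.14
  liver: 0.28
  kidney: 0.78
Vmax_ABCB1_nmol_L_h: 0.0
Km_ABCB1_nmol_L: 6.41
Vmax_met_umol_L_h: 1794.9
Km_met_umol_L: 11.6
Vmax_bil_nmol_L_h: 23.35
Km_bil:
  value: 1.52e-05
  unit: nmol/L
sf_bil: 1.0
PSA_ml_h: 0.379
GFR_fraction: 0.11
fu: 1.0
fraction_bound_plasma: 0.75
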
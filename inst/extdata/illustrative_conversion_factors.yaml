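schema: radoncrisk/conversion_factors/v1
radiograph_msv:
  chest: 0.02
  abdomen: 0.7
  pelvis: 0.6
  head: 0.05
  neck: 0.1
  limb: 0.01
  spine: 1.0
fluoro_k_msv_per_mgycm2:
  chest: 0.0018
  abdomen: 0.0026
  pelvis: 0.0026
  head: 0.0008
  neck: 0.0012
  limb: 0.0006
  spine: 0.0022
ct_k_msv_per_mgycm:
  chest: 0.014
  abdomen: 0.015
  pelvis: 0.015
  head: 0.0021
  neck: 0.0059
  limb: 0.0008
  spine: 0.01
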
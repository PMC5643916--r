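# Published density assignments (kg m^-3) used in the composite-CoM
# sensitivity analysis. Air cavities always subtract at the density of the
# flesh segment displacing them, so the uniform 1000 set reproduces the
# conventional "flesh 1000 / air 0" treatment. Limb values in D6/D7 are
# averages over all segments of that limb, stored as single per-limb values.
D1:            # uniform best guess
  flesh: 1000
D2:            # homogeneous bird flesh, maximum density
  flesh: 1069
D3:            # homogeneous bird flesh, minimum density
  flesh: 536.8
D4:            # bird/archosaur segment densities
  head_and_neck: 300
  trunk: 800
  limbs: 1000
D5:            # bird/archosaur segment densities
  head: 1000
  neck: 600
  trunk: 850
  limbs: 1050
D6:            # human segment densities
  head_and_neck: 1170.8
  trunk: 1013.8
  forelimbs: 1080
  hindlimbs: 1062
D7:            # horse segment densities
  head: 1031
  neck: 1038
  trunk: 850
  forelimbs: 1155
  hindlimbs: 1170
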
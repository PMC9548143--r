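# Biome parameter overrides. Any field omitted falls back to the package
# defaults (defaultBiomeParams()). Units: c_max g C m-2 month-1;
# temperatures degC; k_c ppm; r_m, l_f, k_d month-1; r_g fraction;
# q10_* dimensionless; cloud_ext dimensionless.
forest:
  c_max: 150
  t_min: -5
  t_opt: 25
  t_max: 40
shrubland:
  c_max: 60
grassland:
  c_max: 70
wetland:
  c_max: 90
cropland:
  c_max: 110
  t_min: 1
  t_opt: 25
bare:
  c_max: 5
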
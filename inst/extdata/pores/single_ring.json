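{
  "geometry": {"radius_nm": 0.7, "length_nm": 10},
  "charges": [{"z_nm": 8.5, "valence": -1, "multiplicity": 7}],
  "electrolyte": {"molar": 1, "temperature_K": 298,
                  "D_cation": 1.957e-9, "D_anion": 2.032e-9}
}
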
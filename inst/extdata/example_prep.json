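{
  "dry_mass_ashed_mg": 100,
  "suspension_volume_ml": 100,
  "filtered_volume_ml": 20,
  "active_area_mm2": 222,
  "field_area_mm2": 0.0001,
  "magnification": 12000
}
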
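{
  "name": "oxcom6-demo",
  "seed": 3841,
  "n_events": 20000,
  "strains": ["R", "Y", "B", "RY", "RB", "YB"],
  "proportions": [0.16666666666666666, 0.16666666666666666,
                  0.16666666666666666, 0.16666666666666666,
                  0.16666666666666666, 0.16666666666666669],
  "subtract_background": true,
  "background": {"n_events": 10000, "n_replicates": 3, "plant": "pea"},
  "samples": [
    {"sample_id": "pea_7dpi_r1", "timepoint": 7,
     "acquisition_time_min": 10, "flow_rate_uL_min": 3.66,
     "harvest_volume_mL": 25, "root_mass_g": 0.5, "plant": "pea",
     "replicate": 1},
    {"sample_id": "pea_7dpi_r2", "timepoint": 7,
     "acquisition_time_min": 10, "flow_rate_uL_min": 3.66,
     "harvest_volume_mL": 25, "root_mass_g": 0.62, "plant": "pea",
     "replicate": 2},
    {"sample_id": "pea_14dpi_r1", "timepoint": 14,
     "acquisition_time_min": 10, "flow_rate_uL_min": 3.66,
     "harvest_volume_mL": 25, "root_mass_g": 0.81, "plant": "pea",
     "replicate": 1}
  ]
}
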
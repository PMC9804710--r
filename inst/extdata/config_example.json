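{
  "source": {
    "thermal_fraction": 0.02,
    "epithermal_fraction": 0.88,
    "fast_fraction": 0.10,
    "disc_radius": 7,
    "angular_exponent": 2
  },
  "geometry": {
    "filter": {"design": "C", "disc_thickness_mm": 5,
               "square_side_cm": 8, "square_thickness_mm": 5},
    "phantom_material": "brain_icrp",
    "collimator_diameter_cm": 12
  },
  "transport": {
    "n_particles": 200000,
    "seed": 7,
    "n_batches": 20,
    "bin_cm": 0.5
  },
  "outputs": {"dir": "results"}
}
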
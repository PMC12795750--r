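{
  "generator": {
    "n_metro_areas": 3,
    "tracts_per_metro": 50,
    "nonmetro_tracts": 80,
    "blocks_per_tract": [8, 20],
    "mean_tract_population": 4000,
    "minority_cluster_strength": 1.5,
    "beta_transport": 5,
    "beta_occupation": 1,
    "redline_fraction": 0.3,
    "discrimination_fraction": 0.5
  },
  "transport": {
    "threshold": 55,
    "level_uncertainty_sd": 2,
    "n_iterations": 300
  },
  "workplace_iterations": 300,
  "bootstrap_n": 100,
  "quintile_mode": "per_metro"
}
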
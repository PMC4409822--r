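{
  "theta": 0.30,
  "epsilon": 0.8,
  "cohort_size": 2,
  "n_cohorts": 20,
  "strategy": "closest",
  "selection": "min_sample_size",
  "constraint": "neighbourhood",
  "coherence": false,
  "start_dose": [1, 1],
  "seed": 1,
  "median_grid_file": "study1_medians.csv",
  "strength": 0.027777777777777776,
  "row_order": "descending"
}
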
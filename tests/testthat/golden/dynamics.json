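{
  "s1_vs_s2": {
    "mean_abs_delta": 0.97,
    "frac_delta_within_2": 0.95,
    "similarity_observed": 0.8950955727,
    "similarity_null_mean": 0.0152997374,
    "recruitment_rate": 0.1111111111,
    "reoccurrence": [0.4, 0.4444444444, 0.8333333333],
    "novel_high_n": 1,
    "novel_high_mean_gain": 2.8
  },
  "s1_vs_s3": {
    "mean_abs_delta": 1.25,
    "frac_delta_within_2": 0.9,
    "similarity_observed": 0.8097858377,
    "similarity_null_mean": 0.0112944514,
    "recruitment_rate": 0.1111111111,
    "reoccurrence": [0.2, 0.6666666667, 0.8333333333],
    "novel_high_n": 1,
    "novel_high_mean_gain": 5.2
  }
}
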
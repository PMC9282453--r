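{
  "n": 105,
  "female_fraction": 0.4095238095238095,
  "base_aorta": 3.942,
  "base_pv": 4.479,
  "female_vessel_multiplier": 1.27,
  "circulatory_cv": 0.18,
  "target_mixed_mean": 2.10,
  "uptake_age_slope": -0.0056,
  "uptake_cv": 0.14,
  "roi_cv": 0.03,
  "vessel_cv": 0.05,
  "seed": 42
}
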
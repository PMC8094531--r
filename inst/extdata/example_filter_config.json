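{
  "comment": "Example stop-n-gram filter thresholds calibrated on the synthetic corpus generator at its default 20-specialty setting. The natural scale is the uniform local-relevance share: a term spread evenly over k specialties has LRM close to 1/k in each of them with near-zero dispersion, so threshold_max = 3/k and threshold_sd = 0.4/k (see example_filter_thresholds()). Both are strict upper bounds; min_specialty_count = null means floor(0.9 * k).",
  "num_specialties": 20,
  "threshold_sd": 0.02,
  "threshold_max": 0.15,
  "min_specialty_count": null
}
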
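{
  "intercept": 7,
  "coefficients": {
    "D001": 1.5,
    "D006": -1.2,
    "D011": 0.8
  },
  "note": "synthetic pinned study-like dataset (generator seed 20170519)",
  "spec": {
    "n_compounds": 25,
    "n_descriptors": 60,
    "true_subset_size": 3,
    "true_intercept": 7,
    "true_coefficients": [1.5, -1.2, 0.8],
    "noise_sd": 0.9,
    "block_correlation": 0.5,
    "block_size": 5,
    "n_test": 6,
    "seed": 20170519
  }
}
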
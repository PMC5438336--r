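{
  "pim1": {
    "intercept": 6.92,
    "coefficients": {"AATS0p": -5.84, "maxHBint8": -0.27, "GATS8v": 1.072},
    "note": "PIM1 literature MLR (N=19); GATS8v printed as 1072 in the source, corrected to 1.072 (order-one Geary autocorrelation; printed value off the pIC50 scale)"
  },
  "pim2": {
    "intercept": -32.31,
    "coefficients": {"GATS8v": 12.8, "AATS3i": 0.16, "VR1_Dzm": -8.48},
    "note": "PIM2 literature MLR (N=19), coefficients as printed"
  }
}
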
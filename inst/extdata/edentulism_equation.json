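{
  "description": "Reference 7-variable prediction equation for 12-year incident edentulism (HRS 2006 baseline, 2018 outcome), recalibrated on the selection set. p = exp(L)/(1+exp(L)); A is age in years / 10, all other terms 0/1 indicators.",
  "intercept": -4.866,
  "coefficients": {
    "R1": 0.472,
    "R2": 0.322,
    "R3": -0.130,
    "G": 0.078,
    "A": 0.158,
    "E0": 0.908,
    "E1": 0.646,
    "S0": 1.261,
    "S1": 0.389,
    "D": 0.850,
    "C": 0.599
  }
}
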
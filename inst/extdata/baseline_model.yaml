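# Default baseline-toxicity (narcosis) QSAR coefficients:
#   log10 EC50 [mg/L] = slope * logKow + intercept, per BQE.
# These are generic narcosis-style values shipped as a documented starting
# point; they are data, not code. Replace them with coefficients fitted for
# your compound domain before interpreting predicted toxic units on real
# samples.
slopes:
  algae: -0.91
  crustacean: -0.82
  fish: -0.86
intercepts:
  algae: 1.72
  crustacean: 1.48
  fish: 1.55
cap_tolerance: 0.5
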
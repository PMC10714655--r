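# Example continuous-exposure intervention scenario: a nutrition-education
# intervention acting on determinants of fruit intake. Weights are the signed
# causal impacts of the intervention node on its target determinants.
name: basic
mode: continuous
activation: 1.0
weights:
  awareness: 0.591
  attitude: 0.340
  attitude_price: -0.340
  self_efficacy_1: 0.500
  self_efficacy_2: 0.058
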
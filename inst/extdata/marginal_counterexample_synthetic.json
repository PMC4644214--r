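{
  "description": "Synthetic witness generated by netEntropy::marginalWeakeningCounterexample(p=3): element-wise weakening of marginal correlations that DECREASES entropy, showing the conditional-dependence monotonicity has no marginal analogue.",
  "corBase": [
    [1, -0.0823063282709057, 0.0289978464717021],
    [-0.0823063282709057, 1, -0.446798804439514],
    [0.0289978464717021, -0.446798804439514, 1]
  ],
  "gammaLow": [1, 0.290101220132783, 1],
  "gammaHigh": [1, 1, 1],
  "entropyLow": -0.230489914204593,
  "entropyHigh": -0.229553580984864
}
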
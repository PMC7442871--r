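# Example scenario: alternative visual-field slope, undiscounted.
# Any field not given here keeps its published base-case default.
progression:
  vf_slope: -24.3
costs:
  discount: {rate_costs: 0.0, rate_qalys: 0.0}
n_sims: 100
master_seed: 42
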
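# Deterministic invasion-fitness landscape around a symmetric resident.
experiment:
  name: landscape
  resident: [1, 1, 0, 0]
  grid_step: 0.05
kinetics:
  k_on: 1.0
  k_off: 1.0
  deg: 0.5
  n_cost: 1
evolution:
  N: 1000
out_dir: results
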
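# Steady-state symmetry across fixed recombination rates.
experiment:
  name: sweep
  rho_grid: [0.0, 0.1, 0.2, 0.3, 0.4, 0.5]
kinetics:
  k_on: 3.0
  k_off: 1.0
  deg: 0.5
  n_cost: 1
evolution:
  N: 1000
  mu: 0.01
  sigma: 0.1
  max_generations: 20000
seed: 1
out_dir: results
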
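# Coevolution of signaling asymmetry and the recombination modifier.
experiment:
  name: linkage
  drift_generations: 1000
kinetics:
  k_on: 10.0
  k_off: 1.0
  deg: 0.5
  n_cost: 1
evolution:
  N: 1000
  mu: 0.01
  sigma: 0.1
  mu_rho: 0.01
  sigma_rho: 0.1
  max_generations: 20000
seed: 1
out_dir: results
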
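# Asymmetric equilibrium (E2): strong within-cell binding drives the
# population into two complementary sender/receiver mating types.
experiment:
  name: equilibrium
  rho_fixed: 0.0
kinetics:
  k_on: 5.0
  k_off: 1.0
  deg: 0.1
  n_cost: 1
evolution:
  N: 1000
  mu: 0.01
  sigma: 0.1
  max_generations: 10000
seed: 1
out_dir: results
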
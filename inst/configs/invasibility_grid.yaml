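# Pairwise-invasibility heatmap over mutant deviations (dx, dy).
experiment:
  name: grid
  family: two_mutants
  dx: [0.0, 0.25, 0.5, 0.75, 1.0]
  dy: [0.0, 0.25, 0.5, 0.75, 1.0]
  p: 0.01
kinetics:
  k_on: 10.0
  k_off: 1.0
  deg: 0.1
  n_cost: 1
evolution:
  N: 1000
  mu: 0.0
  max_generations: 10000
  epsilon_s: 1.0e-7
replicates: 5
seed: 1
out_dir: results
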
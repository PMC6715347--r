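---
title: "The gamsig model: within-cell signaling kinetics and the evolution of mating types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gamsig model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gamsig` simulates how self-incompatible gamete classes — mating types —
can arise from selection on cell-to-cell signaling alone, and why the genes
that define them end up in regions of suppressed recombination. This
vignette documents the model, its parameters and defaults, the numerical
choices, and what the simulations do and do not establish.

## Within-cell kinetics

Each cell produces a surface-bound ligand and its receptor. Free ligand
$L$, free receptor $R$ and bound complex $LR$ within one cell follow
mass-action kinetics,

$$
\frac{d[L]}{dt} = \nu_L - k_+[R][L] + k_-[LR] - \gamma_L [L], \qquad
\frac{d[R]}{dt} = \nu_R - k_+[R][L] + k_-[LR] - \gamma_R [R],
$$
$$
\frac{d[LR]}{dt} = k_+[R][L] - k_-[LR] - \gamma_{LR}[LR],
$$

with production rates $\nu_L, \nu_R$, binding/unbinding rates $k_+, k_-$
and degradation rates $\gamma$. Production and turnover are assumed fast
relative to cell encounters, so cells are at kinetic steady state when they
meet. `solve_pair_steady_state()` obtains that steady state in closed
form: eliminating $[LR]$ through the complex balance and substituting the
two flux balances $\nu_L = \gamma_L [L]^* + \gamma_{LR}[LR]^*$ and
$\nu_R = \gamma_R [R]^* + \gamma_{LR}[LR]^*$ leaves a quadratic in
$[LR]^*$ whose smaller root is the unique solution with all three
concentrations non-negative. We solve the quadratic from first principles
rather than transcribing a typeset closed form, and cross-check the root
against long-time stiff ODE integration (`deSolve`) in the test suite
(agreement to $10^{-14}$ relative on random parameter draws; the suite
enforces $10^{-6}$). The root is evaluated in the numerically stable form
$2c/(-b + \sqrt{b^2-4ac})$, which returns exactly zero complex when either
production rate or $k_+$ is zero.

## Between-cell signal and mating probability

When cell 1 contacts cell 2, the signal cell 1 receives is

$$
W_{12} \;=\; k_b\,[L_2]^*[R_1]^*\left(1-\frac{[LR_1]^*}{[LR_1]^* +
k_b[L_2]^*[R_1]^*}\right)^{\!n},
$$

where $k_b$ couples the sender's free ligand to the receiver's free
receptor and $n \ge 0$ sets the cost of self-signaling: with $n = 0$,
self-binding only depletes free molecules; with $n \ge 1$ the receiver also
mis-attributes self-activated complex, discounting the incoming signal by
the fraction of its activation that is partner-derived. When the
cross-product is zero the bracket is taken as its continuous limit and the
contribution is exactly zero. Cells carry **two** mutually incompatible
systems, $(L, R)$ and $(l, r)$, and $W_{12}$ sums their contributions
(`incoming_signal()`).

The probability that the two cells mate is
$P = W_{12}W_{21} / (K + W_{12}W_{21})$. The saturation constant $K$ is
calibrated once per kinetic configuration to the maximum attainable
$W_{12}W_{21}$ so that $P \le 1/2$ and is close to linear in the signal
product for typical genotypes. `calibrate_K()` uses the analytic maximum
$(k_b\,\alpha^2/(\gamma_L\gamma_R))^2$: flux balance bounds every free
concentration by $\nu/\gamma$, the cost bracket by one, and the bilinear
form $L_2R_1 + l_2r_1$ by $\alpha^2$ over the two per-locus production
simplexes; the fully asymmetric complementary pair
$(\alpha,0,0,\alpha)$–$(0,\alpha,\alpha,0)$ attains all three bounds at
once because it forms no self-complex. A dense grid over the eight free
rates of a genotype pair is combinatorially out of reach, so the numerical
confirmation (`verify = TRUE`) is a multistart L-BFGS-B search from a
deterministic low-discrepancy start set; it has never beaten the analytic
candidate, as the bound predicts.

## Evolutionary model

A haploid population of $N$ cells (default 1000) carries a ligand locus
$(\nu_L, \nu_l)$, a receptor locus $(\nu_R, \nu_r)$ and a recombination
modifier $\rho \in [0, 0.5]$. Capacity is shared within a locus:
$\nu_L + \nu_l \le \alpha$ and $\nu_R + \nu_r \le \alpha$ with $\alpha = 1$
by default ($\alpha > 1$ models synergy between the two ligands or
receptors, $\alpha < 1$ competition).

One generation consists of:

1. **Mutation.** Each production gene independently receives a
   $\mathcal N(0, \sigma)$ increment with probability $\mu$ (defaults
   $\mu = 0.01$, $\sigma = 0.1$). Proposals outside $[0, \alpha]$ are
   discarded; if a locus then exceeds its capacity both genes are rescaled
   proportionally, preserving their ratio. The modifier mutates with
   probability $\mu_\rho$ by a $\mathcal N(0, \sigma_\rho)$ increment,
   clamped to $[0, 0.5]$ (a recombination probability; clamping rather
   than rejection because, unlike the production genes, no rejection rule
   is natural for a bounded probability and the boundary values are the
   biologically meaningful extremes). $\sigma_\rho = 0.1$ by default, the
   same scale as the production kernel.
2. **Mating.** Pairs of distinct cells are drawn uniformly from the pool
   of unmated cells and mate with probability $P$; failures return to the
   pool, and sampling repeats until $M$ cells ($M = N/2$ by default) have
   mated.
3. **Recombination.** Each mated pair forms a transient diploid that
   segregates into two complementary haploid offspring. With joint rate
   $\rho_{12} = (\rho_1 + \rho_2)/2$, the offspring pair is
   $\{R_1M_1L_1, R_2M_2L_2\}$ with probability $(1-\rho_{12})^2$,
   $\{R_1M_2L_1, R_2M_1L_2\}$ with $\rho_{12}^2$, and each of
   $\{R_1M_2L_2, R_2M_1L_1\}$ and $\{R_1M_1L_2, R_2M_2L_1\}$ with
   $\rho_{12}(1-\rho_{12})$. The two genes within a locus always travel
   together.
4. **Regulation.** The population returns to size $N$ by sampling the $M$
   offspring with replacement.

Mutation precedes mating, and offspring are not re-mutated within their
birth generation; the life cycle does not pin this order down and we fix
it once. The population state is summarized by the symmetry statistic

$$
s = 1 - \frac{1}{2N}\sum_{i=1}^{N}\left(|\nu_{L_i}-\nu_{R_i}| +
|\nu_{l_i}-\nu_{r_i}|\right) \in [0, 1],
$$

which is 1 for symmetric producers and 0 for a population split into
polarized sender/receiver types.

### Exact acceleration of the mating loop

Literal rejection sampling can need $\sim 1/P$ draws per mating, and
calibrated $P$ values are often $10^{-3}$–$10^{-5}$. `sample_matings()`
therefore accepts with probability $P/P_b$, where
$P_b \ge \max_{\text{pairs}} P$ comes from the per-generation bound
$W \le k_b(\max L \cdot \max R + \max l \cdot \max r)$. Conditional on
acceptance, a drawn pair is distributed proportionally to $P$ under either
scheme, so the sequence of mated pairs is *exactly* equidistributed with
the literal process — only the number of rejected draws changes. Plain
mode (`envelope = FALSE`) is retained, and the test suite checks both the
distributional equality of the two modes and, in plain mode, that the
realized acceptance rate matches $P$. A generation that exhausts the
attempt cap (default $10^8$ draws) aborts with a diagnostic: a population
in which no pair is compatible cannot complete its life cycle and is not
viable.

Per-cell steady states are deterministic functions of the genotype and are
recomputed once per generation for all cells (two closed-form solves per
cell); all pair evaluations inside the mating loop reuse them.

### Convergence

Runs are declared at mutation–selection balance when the trailing
100-generation window of $s$ (and of mean $\rho$ where the modifier
evolves) varies by less than $\epsilon = 10^{-5}$ ($10^{-7}$ for invasion
experiments), checked every 100 generations. We use window *stability*
rather than a single lagged difference: under recurrent mutation $s$
fluctuates by $\sim 10^{-3}$ per 100 generations, and a single-lag test
would trigger spuriously with probability of order
$\epsilon/\mathrm{noise}$ per check. A consequence worth knowing is that
runs with recurrent mutation essentially always end at the generation cap,
which is the intended behavior for noisy steady states; invasion runs,
where mutation is off, converge exactly once frequencies settle. Reported
steady-state values (`s_star`, `rho_star`) average the trailing 1000
generations.

## Experiments

* `equilibrium_experiment()` — monomorphic $(1,1,0,0)$ start, fixed
  recombination. Depending on $k_+$ and $\gamma$ the population stays
  symmetric (E1, $s^* \approx 1$) or splits into complementary
  $(1,0,0,1)$/$(0,1,1,0)$ mating types (E2, $s^* \approx 0$).
* `invasion_experiment()` / `invasibility_grid()` — adaptive-dynamics
  runs: mutants at frequency $p$, no recurrent mutation, strict
  convergence. Single asymmetric mutants never spread; complementary
  pairs of sufficient effect take over to 50/50.
* `recombination_sweep()` — $s^*(\rho)$ at fixed recombination rates; at
  high $\rho$ the population settles at the recombination-proof mixed
  equilibrium ($s^* = 0.5$) in which one locus fixes both genes at
  $\alpha/2$ and the other stays polarized.
* `linkage_coevolution()` — modifier initialized at $\rho = 0.5$, 1000
  generations of drift, then production-rate mutation switches on. Under
  parameters favoring asymmetry the modifier hitchhikes to $\rho^* \to 0$
  (suppressed recombination); otherwise it drifts over its full range
  like a neutral allele.

Problem sizes used by the acceptance script and the simulation tests:
$N = 1000$, $M = 500$, caps of $10^4$ generations for the plain
equilibrium runs and $2\times 10^4$ for the recombination and linkage
runs, five replicates for the invasion experiment. These are the
configurations at which the reported equilibria are well-resolved at
single-CPU scale; the trailing-window averages are insensitive to the cap
once the population has settled.

## Numerical and design notes

* **Tie-breaks and degenerate inputs.** Zero production or $k_+ = 0$
  yields the linear steady state exactly; zero degradation is rejected at
  construction (the steady state would diverge). `bin_genotypes()`
  resolves distance ties deterministically (first archetype in a fixed
  order).
* **Determinism.** All stochastic layers draw from R's RNG; a seed fully
  determines a trajectory. Replicated drivers expand one global seed into
  per-replicate substreams (`substream_seeds()`), so any heatmap cell can
  be reproduced in isolation; the logged seed accompanies every replicate
  row.
* **Mutant families for landscapes.** `invasion_landscape()` offers the
  absolute family $(1-dx, 1-dy, dx, dy)$, in which the resident sits at
  its own coordinates, and a relative family anchored at the resident
  (zero fitness difference at the origin by construction). The absolute
  family is the one used for the sign-structure checks.
* **Initial mutant frequency matters.** In invasion runs the basin of the
  asymmetric equilibrium narrows as $p$ decreases (rare complementary
  mutants must co-segregate to meet); $p$ is an explicit argument
  everywhere rather than a constant.

## Known limitations

* The symmetric equilibrium E1 is only *metastable*: its persistence
  depends on the kinetic parameters and on the mutation kernel. At low
  degradation rates ($\gamma \approx 0.1$) even modest second-system
  production yields large free-ligand pools ($[l]^* = \nu_l/\gamma$), so
  complementary deviant pairs gain a large mating advantage and the
  population can tip to the asymmetric equilibrium within hundreds of
  generations for any appreciable $k_+$ under the default kernel
  ($\mu = 0.01$, $\sigma = 0.1$). At $\gamma = 0.5$ the E1/E2 threshold
  sits between $k_+ = 2$ and $k_+ = 5$ under the defaults. Waiting times
  for such stochastic transitions are kernel- and population-size
  sensitive, and claims about E1 persistence should be read as claims
  about time scales, not absolute stability.
* Signaling is strictly local: no diffusible pheromone field, no spatial
  structure, no cross-binding between the two ligand–receptor systems.
* The diploid phase exists only to recombine; there is no diploid
  selection, and only the three-locus arrangement ligand–modifier–receptor
  (equal flanking distances, a single joint recombination event) is
  modeled.
* The synthetic populations are idealized: real gamete-recognition systems
  have more loci, unequal production capacities and environment-dependent
  expression. Passing tests establish internal consistency of the model's
  kinetics, selection response and linkage dynamics — not quantitative
  predictions for any particular organism.
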
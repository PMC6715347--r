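## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## Long-time ODE integration of the within-cell kinetics (mass action):
## d[L]/dt  = nuL - k_on [L][R] + k_off [LR] - deg_L [L]
## d[R]/dt  = nuR - k_on [L][R] + k_off [LR] - deg_R [R]
## d[LR]/dt = k_on [L][R] - k_off [LR] - deg_LR [LR]
ode_steady_state <- function(nu_L, nu_R, kin, t_end = 5000) {
  f <- function(t, y, p) {
    list(c(nu_L - kin$k_on * y[1] * y[2] + kin$k_off * y[3] - kin$deg_L * y[1],
           nu_R - kin$k_on * y[1] * y[2] + kin$k_off * y[3] - kin$deg_R * y[2],
           kin$k_on * y[1] * y[2] - kin$k_off * y[3] - kin$deg_LR * y[3]))
  }
  out <- deSolve::ode(c(L = 0, R = 0, LR = 0), c(0, t_end), f, NULL,
                      rtol = 1e-12, atol = 1e-12)
  as.numeric(out[2, 2:4])
}

## Scalar re-implementation of the directed signal for one cell pair,
## written directly from the formula (receiver subscript 1, sender 2).
w12_oracle <- function(receiver, sender, kb, n) {
  term <- function(L2, R1, B1) {
    cross <- kb * L2 * R1
    if (cross == 0) return(0)
    cross * (1 - B1 / (B1 + cross))^n
  }
  term(sender$pair_LR$L_free, receiver$pair_LR$R_free, receiver$pair_LR$LR_bound) +
    term(sender$pair_lr$L_free, receiver$pair_lr$R_free, receiver$pair_lr$LR_bound)
}

## Random feasible genotype (respecting the per-locus capacity alpha).
random_genotype <- function(alpha = 1) {
  lig <- stats::runif(2)
  if (sum(lig) > 1) lig <- lig / sum(lig)
  rec <- stats::runif(2)
  if (sum(rec) > 1) rec <- rec / sum(rec)
  production_rates(lig[1] * alpha, rec[1] * alpha,
                   lig[2] * alpha, rec[2] * alpha, alpha = alpha)
}

## Small-population shorthand for engine tests.
tiny_params <- function(N = 100, M = N / 2, ...) {
  evolution_params(N = N, M = M, ...)
}
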
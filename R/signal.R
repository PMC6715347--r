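## Between-cell signal strength, mating probability, saturation-constant
## calibration, and deterministic invasion-fitness analysis.

## Vectorized one-direction signal kernel. Receiver quantities: free
## receptors Ri, ri and self complexes Bi, bi; sender quantities: free
## ligands Lj, lj. Each pair contributes
##   kb * Lj * Ri * (kb * Lj * Ri / (Bi + kb * Lj * Ri))^n,
## the bracket being the fraction of the receiver's activated complex that
## originates from the partner. A pair with zero cross product contributes
## exactly 0 (continuous limit of the 0/0 case).
.w12 <- function(Lj, Ri, Bi, lj, ri, bi, kb, n) {
  p1 <- kb * Lj * Ri
  p2 <- kb * lj * ri
  d1 <- Bi + p1
  d2 <- bi + p2
  t1 <- p1 * ifelse(p1 > 0, p1 / d1, 0)^n
  t2 <- p2 * ifelse(p2 > 0, p2 / d2, 0)^n
  t1 + t2
}

#' Strength of the incoming signal between two cells
#'
#' Computes the signal a receiver cell obtains from a sender cell, summed
#' over the two mutually incompatible ligand-receptor systems. For each
#' system the between-cell interaction couples the sender's free ligand to
#' the receiver's free receptor with affinity `k_between`; when the
#' self-signaling cost exponent `n_cost >= 1`, the contribution is weighted
#' by the fraction of the receiver's activated complex that comes from the
#' partner rather than from self-binding. With `n_cost = 0` the signal
#' reduces to `k_between * (L2 * R1 + l2 * r1)` evaluated at the steady
#' states, so self-binding only acts through depletion of free molecules.
#'
#' @param receiver,sender [cell_signal_state()] objects.
#' @param kin a [kinetic_params()] object.
#' @return The non-negative scalar signal strength for the receiver.
#' @export
incoming_signal <- function(receiver, sender, kin) {
  stopifnot(inherits(receiver, "cell_signal_state"),
            inherits(sender, "cell_signal_state"),
            inherits(kin, "kinetic_params"))
  .w12(sender$pair_LR$L_free, receiver$pair_LR$R_free, receiver$pair_LR$LR_bound,
       sender$pair_lr$L_free, receiver$pair_lr$R_free, receiver$pair_lr$LR_bound,
       kin$k_between, kin$n_cost)
}

#' Mating probability from bidirectional signal strengths
#'
#' Two cells mate with probability `P = w12 * w21 / (K + w12 * w21)`: the
#' product of the two incoming signals saturates with constant `K`. With
#' `K` calibrated to the maximum attainable signal product
#' ([calibrate_K()]), `P` never exceeds 1/2 and is approximately linear in
#' the signal product for typical genotypes.
#'
#' @param w12,w21 non-negative signal strengths (may be vectors).
#' @param K saturation constant, > 0.
#' @return Mating probability in `[0, 1)`.
#' @export
mating_probability <- function(w12, w21, K) {
  if (!is.numeric(K) || length(K) != 1 || !is.finite(K) || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  stopifnot(all(w12 >= 0), all(w21 >= 0))
  ww <- w12 * w21
  ww / (K + ww)
}

## product of the two directed signals for a genotype pair (rate vectors)
.signal_product <- function(g1, g2, kin) {
  s1L <- .solve_pair(g1[1], g1[2], kin$k_on, kin$k_off, kin$deg_L, kin$deg_R, kin$deg_LR)
  s1l <- .solve_pair(g1[3], g1[4], kin$k_on, kin$k_off, kin$deg_L, kin$deg_R, kin$deg_LR)
  s2L <- .solve_pair(g2[1], g2[2], kin$k_on, kin$k_off, kin$deg_L, kin$deg_R, kin$deg_LR)
  s2l <- .solve_pair(g2[3], g2[4], kin$k_on, kin$k_off, kin$deg_L, kin$deg_R, kin$deg_LR)
  w12 <- .w12(s2L$L, s1L$R, s1L$B, s2l$L, s1l$R, s1l$B, kin$k_between, kin$n_cost)
  w21 <- .w12(s1L$L, s2L$R, s2L$B, s1l$L, s2l$R, s2l$B, kin$k_between, kin$n_cost)
  unname(w12 * w21)
}

#' Calibrate the saturation constant of the mating probability
#'
#' Sets `K` to the maximum value the signal product `W12 * W21` can attain
#' over all feasible genotype pairs, given the kinetic parameters and the
#' locus capacity `alpha`. The maximum is attained by the fully asymmetric
#' complementary pair `(alpha, 0, 0, alpha)` versus `(0, alpha, alpha, 0)`
#' and equals `(k_between * alpha^2 / (deg_L * deg_R))^2`: flux balance
#' bounds every free concentration by `nu / deg`, the cost bracket by 1, and
#' the bilinear form `L2*R1 + l2*r1` by `alpha^2` over the two production
#' simplexes, and the complementary pair attains all three bounds
#' simultaneously (it has no self-bound complex). When `verify = TRUE` a
#' multistart box-constrained optimization over genotype pairs confirms
#' numerically that no pair beats the analytic maximizer.
#'
#' @param kin a [kinetic_params()] object.
#' @param alpha locus production capacity (default 1).
#' @param verify run the multistart numerical check (default `TRUE`).
#' @param n_starts number of deterministic optimization starts.
#' @return The saturation constant `K` (scalar), with attributes
#'   `maximizer` (the two genotypes, an 8-vector) and `verified`.
#' @examples
#' kin <- kinetic_params(k_on = 5, k_off = 1, deg = 0.1)
#' calibrate_K(kin, verify = FALSE)
#' @export
calibrate_K <- function(kin, alpha = 1, verify = TRUE, n_starts = 24) {
  stopifnot(inherits(kin, "kinetic_params"), alpha > 0)
  if (kin$k_between <= 0)
    stop("calibrate_K requires k_between > 0", call. = FALSE)
  K0 <- (kin$k_between * alpha^2 / (kin$deg_L * kin$deg_R))^2
  maximizer <- c(alpha, 0, 0, alpha, 0, alpha, alpha, 0)
  verified <- NA
  if (verify) {
    ## map x in [0,1]^8 to a feasible genotype pair via stick breaking
    to_pair <- function(x) {
      g <- function(u1, u2) c(u1 * alpha, u2 * (alpha - u1 * alpha))
      lig1 <- g(x[1], x[2]); rec1 <- g(x[3], x[4])
      lig2 <- g(x[5], x[6]); rec2 <- g(x[7], x[8])
      list(g1 = c(lig1[1], rec1[1], lig1[2], rec1[2]),
           g2 = c(lig2[1], rec2[1], lig2[2], rec2[2]))
    }
    obj <- function(x) {
      p <- to_pair(x)
      -.signal_product(p$g1, p$g2, kin)
    }
    ## deterministic low-discrepancy start set (Halton-like by hand)
    halton <- function(i, base) {
      f <- 1; r <- 0
      while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
      r
    }
    bases <- c(2, 3, 5, 7, 11, 13, 17, 19)
    best <- -Inf
    for (s in seq_len(n_starts)) {
      x0 <- vapply(bases, function(b) halton(s, b), numeric(1))
      fit <- tryCatch(
        stats::optim(x0, obj, method = "L-BFGS-B",
                     lower = rep(1e-6, 8), upper = rep(1 - 1e-6, 8)),
        error = function(e) NULL)
      if (!is.null(fit) && -fit$value > best) best <- -fit$value
    }
    verified <- best <= K0 * (1 + 1e-6)
    if (!verified)
      warning("numerical search exceeded the analytic maximum; using the larger value")
    K0 <- max(K0, best)
  }
  structure(K0, maximizer = maximizer, verified = verified)
}

#' Invasion fitness of a rare mutant against a resident
#'
#' Fitness difference of a rare mutant interacting with a common resident,
#' measured through the signal product that governs mating success:
#' `W12*W21` of the resident-mutant interaction minus `W12*W21` of the
#' resident with itself. Positive values mean a rare mutant finds resident
#' partners more readily than residents find each other.
#'
#' @param res,mut [production_rates()] genotypes.
#' @param kin a [kinetic_params()] object.
#' @return Signed scalar fitness difference.
#' @export
invasion_fitness <- function(res, mut, kin) {
  stopifnot(inherits(res, "production_rates"), inherits(mut, "production_rates"))
  .signal_product(unclass(res), unclass(mut), kin) -
    .signal_product(unclass(res), unclass(res), kin)
}

#' Invasion-fitness landscape over mutant deviations
#'
#' Evaluates [invasion_fitness()] over a grid of mutant deviations
#' `(dx, dy)`. Two mutant families are supported. `"canonical"` uses the
#' absolute family `(alpha - dx, alpha - dy, dx, dy)`: `dx` shifts ligand
#' production from L to l and `dy` receptor production from R to r,
#' irrespective of the resident (the resident then sits at its own
#' coordinates in the plane). `"relative"` perturbs the resident itself:
#' `mut = res + (-dx, -dy, +dx, +dy)`, so the origin is always the resident
#' and the fitness difference at `(0, 0)` is exactly 0.
#'
#' @param res resident [production_rates()].
#' @param kin a [kinetic_params()] object.
#' @param dx,dy numeric grids of deviations.
#' @param family `"canonical"` or `"relative"` (see Details).
#' @return A data frame with columns `dx`, `dy`, `fitness_difference`, of
#'   class `"invasion_landscape"`; infeasible grid points are `NA`.
#' @export
invasion_landscape <- function(res, kin,
                               dx = seq(0, 1, by = 0.05),
                               dy = seq(0, 1, by = 0.05),
                               family = c("canonical", "relative")) {
  stopifnot(inherits(res, "production_rates"))
  family <- match.arg(family)
  alpha <- attr(res, "alpha")
  grid <- expand.grid(dx = dx, dy = dy)
  fd <- vapply(seq_len(nrow(grid)), function(i) {
    d <- c(grid$dx[i], grid$dy[i])
    m <- if (family == "canonical") {
      c(alpha - d[1], alpha - d[2], d[1], d[2])
    } else {
      unclass(res) + c(-d[1], -d[2], d[1], d[2])
    }
    if (any(m < -1e-12) || any(m > alpha + 1e-12)) return(NA_real_)
    mut <- production_rates(m[1], m[2], m[3], m[4], alpha = alpha)
    invasion_fitness(res, mut, kin)
  }, numeric(1))
  out <- data.frame(grid, fitness_difference = fd)
  attr(out, "resident") <- unclass(res)
  attr(out, "family") <- family
  class(out) <- c("invasion_landscape", "data.frame")
  out
}

#' Write an invasion landscape to CSV with a JSON parameter sidecar
#'
#' @param x an object returned by [invasion_landscape()].
#' @param path output CSV path; a `.json` sidecar with the resident genotype
#'   and mutant family is written next to it.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "invasion_landscape"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(resident = as.list(attr(x, "resident")),
               family = attr(x, "family"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
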
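## Mating by rejection sampling, recombination between the ligand and
## receptor loci, and population regulation.

## Per-cell steady-state cache for a rates matrix: free ligand, free
## receptor and self complex for both systems.
.signal_cache <- function(rates, kin) {
  sLR <- .solve_pair(rates[, 1], rates[, 2], kin$k_on, kin$k_off,
                     kin$deg_L, kin$deg_R, kin$deg_LR)
  slr <- .solve_pair(rates[, 3], rates[, 4], kin$k_on, kin$k_off,
                     kin$deg_L, kin$deg_R, kin$deg_LR)
  list(L = sLR$L, R = sLR$R, B = sLR$B, l = slr$L, r = slr$R, b = slr$B)
}

## Core pair-sampling loop on a prebuilt cache. Pairs of distinct cells are
## drawn uniformly from the pool of unmated cells and accepted with
## probability P (Eq-level rejection sampling). When `envelope` is TRUE the
## acceptance test uses P / Pb for a per-generation upper bound Pb >= max P:
## conditional on acceptance a pair is drawn proportionally to P either way,
## so the sequence of mated pairs has exactly the same distribution while
## the number of rejected draws shrinks by ~1/Pb. The bound comes from
## W12 <= kb * (max L * max R + max l * max r) over the population (flux
## balance bounds each factor; the cost bracket is <= 1).
.sample_matings <- function(cache, K, params, envelope = TRUE) {
  N <- length(cache$L)
  need <- params$M %/% 2L
  kb <- cache$kb
  n <- cache$n
  if (params$selection) {
    Wb <- kb * (max(cache$L) * max(cache$R) + max(cache$l) * max(cache$r))
    if (Wb <= 0)
      stop("population is all-incompatible: no pair has positive mating probability",
           call. = FALSE)
    Pb <- if (envelope) Wb^2 / (K + Wb^2) else 1
  } else {
    Pb <- 1
  }
  mated <- logical(N)
  pairs <- matrix(0L, need, 2)
  got <- 0L
  attempts <- 0
  batch <- max(1000L, 4L * need)
  while (got < need) {
    i <- sample.int(N, batch, replace = TRUE)
    j <- sample.int(N, batch, replace = TRUE)
    ok <- i != j
    if (params$selection) {
      w12 <- .w12(cache$L[j], cache$R[i], cache$B[i],
                  cache$l[j], cache$r[i], cache$b[i], kb, n)
      w21 <- .w12(cache$L[i], cache$R[j], cache$B[j],
                  cache$l[i], cache$r[j], cache$b[j], kb, n)
      ww <- w12 * w21
      P <- ww / (K + ww)
      acc <- ok & (stats::runif(batch) < P / Pb)
    } else {
      acc <- ok
    }
    kstop <- batch
    for (k in which(acc)) {
      a <- i[k]; b <- j[k]
      if (mated[a] || mated[b]) next
      got <- got + 1L
      pairs[got, 1L] <- a
      pairs[got, 2L] <- b
      mated[a] <- TRUE
      mated[b] <- TRUE
      if (got == need) {
        kstop <- k
        break
      }
    }
    attempts <- attempts + sum(ok[seq_len(kstop)])
    if (got < need && attempts > params$mate_attempt_cap)
      stop(sprintf(paste0("mating attempt cap exceeded (%g draws, %d of %d pairs ",
                          "formed): the population cannot complete its matings"),
                   attempts, got, need), call. = FALSE)
    ## grow the batch when acceptance is scarce
    rate <- max(got / max(attempts, 1), 1e-6)
    batch <- as.integer(min(max(1000, 2 * (need - got) / rate), 2e5))
  }
  list(pairs = pairs, attempts = attempts)
}

#' Sample the mated pairs of one generation
#'
#' Implements the mating phase of the life cycle: pairs of distinct cells
#' are drawn at random from the pool of unmated cells and mate with
#' probability given by [mating_probability()] evaluated on their cached
#' signal states; cells that fail return to the pool, and the process
#' repeats until `M` cells (i.e. `M/2` pairs) have mated. A population in
#' which no pair can mate (for example, all cells fully asymmetric in the
#' same direction) aborts with an error once the attempt cap is reached.
#'
#' The default `envelope = TRUE` accelerates the rejection loop by scaling
#' all acceptance probabilities with a common upper bound, which leaves the
#' distribution of the sampled pairs exactly unchanged (conditional on
#' acceptance, a pair is drawn proportionally to its `P` either way).
#'
#' @param pop a [cell_population()].
#' @param kin a [kinetic_params()] object.
#' @param K calibrated saturation constant (see [calibrate_K()]).
#' @param params an [evolution_params()].
#' @param envelope use the exact envelope acceleration (default `TRUE`).
#' @return A list with `pairs` (an `M/2 x 2` integer matrix of cell
#'   indices) and `attempts` (number of pair draws consumed).
#' @export
sample_matings <- function(pop, kin, K, params, envelope = TRUE) {
  stopifnot(inherits(pop, "cell_population"), inherits(kin, "kinetic_params"),
            inherits(params, "evolution_params"))
  if (nrow(pop$rates) != params$N)
    stop("population size does not match params$N", call. = FALSE)
  cache <- .signal_cache(pop$rates, kin)
  cache$kb <- kin$k_between
  cache$n <- kin$n_cost
  .sample_matings(cache, K, params, envelope = envelope)
}

## Vectorized recombination of mated pairs. Loci: receptor (nu_R, nu_r),
## modifier rho, ligand (nu_L, nu_l). The joint recombination probability of
## a pair is the mean of the two modifier alleles; one of four offspring
## configurations is drawn per pair:
##   R1-M1-L1 / R2-M2-L2   with (1 - rho)^2   (no recombination)
##   R1-M2-L1 / R2-M1-L2   with rho^2         (two events)
##   R1-M2-L2 / R2-M1-L1   with rho (1 - rho) (one event)
##   R1-M1-L2 / R2-M2-L1   with rho (1 - rho) (one event)
## Offspring 1 always carries the receptor locus of parent 1; ligand-locus
## genes travel together, as do receptor-locus genes.
.recombine <- function(rates, rho, pairs) {
  p1 <- pairs[, 1L]
  p2 <- pairs[, 2L]
  npair <- length(p1)
  rj <- (rho[p1] + rho[p2]) / 2
  u <- stats::runif(npair)
  c1 <- (1 - rj)^2
  c2 <- c1 + rj^2
  c3 <- c2 + rj * (1 - rj)
  cfg <- ifelse(u < c1, 1L, ifelse(u < c2, 2L, ifelse(u < c3, 3L, 4L)))
  lig_from1 <- cfg <= 2L          # offspring 1 ligand locus from parent 1
  mod_from1 <- cfg == 1L | cfg == 4L
  lig1 <- ifelse(lig_from1, p1, p2)
  lig2 <- ifelse(lig_from1, p2, p1)
  m1 <- ifelse(mod_from1, p1, p2)
  m2 <- ifelse(mod_from1, p2, p1)
  off_rates <- cbind(
    nu_L = c(rates[lig1, 1L], rates[lig2, 1L]),
    nu_R = c(rates[p1, 2L], rates[p2, 2L]),
    nu_l = c(rates[lig1, 3L], rates[lig2, 3L]),
    nu_r = c(rates[p1, 4L], rates[p2, 4L]))
  list(rates = off_rates, rho = c(rho[m1], rho[m2]))
}

#' Recombine one mated pair into its two offspring
#'
#' The diploid zygote of two haploid parents recombines between the ligand
#' locus (carrying `nu_L` and `nu_l`), the modifier locus and the receptor
#' locus (carrying `nu_R` and `nu_r`) with joint probability equal to the
#' mean of the parents' modifier alleles, and segregates into two
#' complementary haploid offspring. With `rho = 0` the offspring are copies
#' of the parents; with `rho = 0.5` each of the four configurations is
#' equally likely.
#'
#' @param parent1,parent2 lists with components `rates` (length-4 vector:
#'   `nu_L`, `nu_R`, `nu_l`, `nu_r`) and `rho`.
#' @return A list of two offspring in the same format.
#' @export
recombine_pair <- function(parent1, parent2) {
  rates <- rbind(parent1$rates, parent2$rates)
  off <- .recombine(rates, c(parent1$rho, parent2$rho),
                    matrix(c(1L, 2L), 1))
  list(offspring1 = list(rates = off$rates[1, ], rho = off$rho[1]),
       offspring2 = list(rates = off$rates[2, ], rho = off$rho[2]))
}

#' Regulate a pool of offspring back to the population size
#'
#' The `M` offspring of the mated pairs are sampled uniformly with
#' replacement until the population is restored to `N` cells.
#'
#' @param offspring a [cell_population()] holding the offspring pool.
#' @param N target population size.
#' @return A [cell_population()] of exactly `N` cells.
#' @export
regulate <- function(offspring, N) {
  stopifnot(inherits(offspring, "cell_population"))
  m <- nrow(offspring$rates)
  if (m == 0L) stop("empty offspring pool", call. = FALSE)
  idx <- sample.int(m, N, replace = TRUE)
  offspring$rates <- offspring$rates[idx, , drop = FALSE]
  offspring$rho <- offspring$rho[idx]
  offspring
}
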
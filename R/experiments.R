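## Scenario drivers: equilibrium evolution, rare-mutant invasion,
## invasibility grids, recombination sweeps and linkage coevolution.

#' Expand one seed into reproducible per-replicate substream seeds
#'
#' Replicated experiments draw one seed per replicate from a deterministic
#' expansion of the global seed, so that any single replicate of a sweep or
#' grid can be reproduced in isolation without running the ones before it.
#' The caller's RNG state is left untouched.
#'
#' @param seed global integer seed (or `NULL` for unseeded runs).
#' @param n number of substream seeds.
#' @return Integer vector of length `n` (all `NA` if `seed` is `NULL`).
#' @export
substream_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(NA_integer_, n))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.seed_if <- function(seed) if (!is.null(seed) && !is.na(seed)) set.seed(seed)

#' Equilibrium evolution from a monomorphic start
#'
#' Initializes a monomorphic population, fixes the recombination rate at
#' `rho_fixed` (modifier mutation disabled), and runs to mutation-selection
#' balance. This is the basic experiment in which a symmetric-signaling
#' population either persists (equilibrium E1, `s* ~ 1`) or splits into two
#' complementary asymmetric mating types (E2, `s* ~ 0`), depending on the
#' kinetic parameters.
#'
#' @param kin a [kinetic_params()] object.
#' @param params an [evolution_params()].
#' @param init initial genotype (length-4 vector or [production_rates()]),
#'   default `(1, 1, 0, 0)`.
#' @param rho_fixed fixed recombination rate between the ligand and
#'   receptor loci (default 0).
#' @param seed optional RNG seed.
#' @return An `"evo_run"` object (see [run_to_steady_state()]).
#' @export
equilibrium_experiment <- function(kin, params, init = c(1, 1, 0, 0),
                                   rho_fixed = 0, seed = NULL) {
  stopifnot(rho_fixed >= 0, rho_fixed <= 0.5)
  params$mu_rho <- 0
  .seed_if(seed)
  pop <- cell_population(params$N, init, rho = rho_fixed, alpha = params$alpha)
  run_to_steady_state(pop, kin, params)
}

#' Specification of a rare-mutant invasion experiment
#'
#' @param resident resident genotype (length-4 vector or
#'   [production_rates()]).
#' @param mutants a list of mutant genotypes.
#' @param p initial frequency of each mutant, in (0, 1); the sum over
#'   mutants must stay below 1.
#' @param criterion convergence criterion; invasion runs use a strict
#'   stability threshold of `1e-7` by default because `s` becomes exactly
#'   constant once frequencies settle.
#' @return An object of class `"invasion_spec"`.
#' @export
invasion_spec <- function(resident, mutants, p = 0.01,
                          criterion = convergence_criterion(epsilon_s = 1e-7)) {
  if (!is.list(mutants)) mutants <- list(mutants)
  p <- rep_len(p, length(mutants))
  stopifnot(all(p >= 0), all(p < 1), sum(p) < 1,
            inherits(criterion, "convergence_criterion"))
  structure(list(resident = resident, mutants = mutants, p = p,
                 criterion = criterion),
            class = "invasion_spec")
}

#' Rare-mutant invasion experiment
#'
#' Introduces one or more mutant genotypes at low frequency into a resident
#' population and follows their fate without recurrent mutation
#' (`mu = mu_rho = 0`) until genotype frequencies settle. Exact genotype
#' frequencies in the final population are reported, along with the
#' steady-state symmetry.
#'
#' @param spec an [invasion_spec()].
#' @param kin a [kinetic_params()] object.
#' @param params an [evolution_params()].
#' @param rho_fixed fixed recombination rate for the run (default 0).
#' @param seed optional RNG seed.
#' @return A list of class `"invasion_result"`: `f_resident`, `f_mutants`
#'   (vector), `f_other` (recombinants or extinct classes), `s_star`, and
#'   the underlying `run`.
#' @export
invasion_experiment <- function(spec, kin, params, rho_fixed = 0, seed = NULL) {
  stopifnot(inherits(spec, "invasion_spec"))
  params$mu <- 0
  params$mu_rho <- 0
  params$convergence <- spec$criterion
  .seed_if(seed)
  N <- params$N
  counts <- round(spec$p * N)
  rates <- matrix(rep(as.numeric(unclass(spec$resident))[1:4], each = N),
                  N, 4)
  at <- 0L
  for (k in seq_along(spec$mutants)) {
    if (counts[k] == 0L) next
    rows <- at + seq_len(counts[k])
    rates[rows, ] <- matrix(rep(as.numeric(unclass(spec$mutants[[k]]))[1:4],
                                each = counts[k]), counts[k], 4)
    at <- at + counts[k]
  }
  pop <- cell_population(N, rates, rho = rho_fixed, alpha = params$alpha)
  run <- run_to_steady_state(pop, kin, params)
  final <- run$population$rates
  match_geno <- function(g) {
    g <- as.numeric(unclass(g))[1:4]
    mean(abs(final[, 1] - g[1]) + abs(final[, 2] - g[2]) +
           abs(final[, 3] - g[3]) + abs(final[, 4] - g[4]) < 1e-12)
  }
  f_res <- match_geno(spec$resident)
  f_mut <- vapply(spec$mutants, match_geno, numeric(1))
  structure(list(f_resident = f_res, f_mutants = f_mut,
                 f_other = max(0, 1 - f_res - sum(f_mut)),
                 s_star = run$s_star, run = run),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Invasion experiment: resident %.3f, mutants %s, s* = %.4f\n",
              x$f_resident,
              paste(sprintf("%.3f", x$f_mutants), collapse = "/"),
              x$s_star))
  invisible(x)
}

#' Pairwise-invasibility grid over mutant deviations
#'
#' Runs [invasion_experiment()] for every combination of deviations
#' `(dx, dy)` and several replicates, for one of three resident/mutant
#' families:
#' \describe{
#'   \item{`"two_mutants"`}{resident `(1,1,0,0)` challenged jointly by the
#'     ligand mutant `(1-dx, 1, dx, 0)` and the receptor mutant
#'     `(1, 1-dy, 0, dy)`.}
#'   \item{`"receptor_mutant"`}{resident `(1-dx, 1, dx, 0)` challenged by
#'     `(1, 1-dy, 0, dy)`.}
#'   \item{`"balanced"`}{resident `(0.5-dx, 0.5, 0.5+dx, 0.5)` challenged by
#'     `(0.5, 0.5-dy, 0.5, 0.5+dy)`.}
#' }
#'
#' @param dx,dy numeric grids of deviations.
#' @param kin a [kinetic_params()] object.
#' @param params an [evolution_params()].
#' @param p initial mutant frequency.
#' @param replicates independent replicates per grid point (default 20).
#' @param family one of `"two_mutants"`, `"receptor_mutant"`, `"balanced"`.
#' @param rho_fixed fixed recombination rate.
#' @param seed global seed, expanded into per-replicate substreams.
#' @return A long-format data frame with columns `dx`, `dy`, `replicate`,
#'   `seed`, `s_star`, `f_resident`, `f_mut1`, `f_mut2`.
#' @export
invasibility_grid <- function(dx, dy, kin, params, p = 0.01, replicates = 20,
                              family = c("two_mutants", "receptor_mutant",
                                         "balanced"),
                              rho_fixed = 0, seed = NULL) {
  family <- match.arg(family)
  grid <- expand.grid(dx = dx, dy = dy)
  seeds <- substream_seeds(seed, nrow(grid) * replicates)
  out <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    d <- c(grid$dx[i], grid$dy[i])
    fam <- switch(family,
      two_mutants = list(res = c(1, 1, 0, 0),
                         muts = list(c(1 - d[1], 1, d[1], 0),
                                     c(1, 1 - d[2], 0, d[2]))),
      receptor_mutant = list(res = c(1 - d[1], 1, d[1], 0),
                             muts = list(c(1, 1 - d[2], 0, d[2]))),
      balanced = list(res = c(0.5 - d[1], 0.5, 0.5 + d[1], 0.5),
                      muts = list(c(0.5, 0.5 - d[2], 0.5, 0.5 + d[2]))))
    spec <- invasion_spec(fam$res, fam$muts, p = p)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      res <- invasion_experiment(spec, kin, params, rho_fixed = rho_fixed,
                                 seed = seeds[k])
      out[[k]] <- data.frame(
        dx = d[1], dy = d[2], replicate = r, seed = seeds[k],
        s_star = res$s_star, f_resident = res$f_resident,
        f_mut1 = res$f_mutants[1],
        f_mut2 = if (length(res$f_mutants) > 1) res$f_mutants[2] else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Steady-state symmetry across fixed recombination rates
#'
#' Runs [equilibrium_experiment()] at each fixed recombination rate in
#' `rho_grid`, with replicates, and tabulates the steady-state symmetry.
#' Recombination between the ligand and receptor loci breaks up the
#' co-adapted sender/receiver haplotypes of the asymmetric equilibrium, so
#' `s*` rises with `rho` once asymmetry evolves.
#'
#' @param rho_grid recombination rates to scan.
#' @param kin a [kinetic_params()] object.
#' @param params an [evolution_params()].
#' @param replicates replicates per grid point.
#' @param init initial genotype.
#' @param seed global seed, expanded into substreams.
#' @return Data frame with columns `rho`, `replicate`, `seed`, `s_star`,
#'   `converged`.
#' @export
recombination_sweep <- function(rho_grid, kin, params, replicates = 1,
                                init = c(1, 1, 0, 0), seed = NULL) {
  seeds <- substream_seeds(seed, length(rho_grid) * replicates)
  out <- vector("list", length(rho_grid) * replicates)
  k <- 0L
  for (i in seq_along(rho_grid)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      run <- equilibrium_experiment(kin, params, init = init,
                                    rho_fixed = rho_grid[i], seed = seeds[k])
      out[[k]] <- data.frame(rho = rho_grid[i], replicate = r,
                             seed = seeds[k], s_star = run$s_star,
                             converged = run$converged)
    }
  }
  do.call(rbind, out)
}

#' Coevolution of signaling asymmetry and the recombination modifier
#'
#' Starts a monomorphic `(1, 1, 0, 0)` population with all modifier alleles
#' at the maximal recombination rate `rho = 0.5`, lets the modifier evolve
#' by drift alone for `drift_generations` (production-rate mutation off),
#' then enables production-rate mutation and runs to joint stability of `s`
#' and the mean modifier value. When asymmetric mating types evolve,
#' recombinant offspring are maladapted and modifier alleles that suppress
#' recombination hitchhike to fixation; when symmetry persists the modifier
#' remains neutral and wanders over its range.
#'
#' @param kin a [kinetic_params()] object.
#' @param params an [evolution_params()]; `mu_rho` should be positive.
#' @param drift_generations length of the drift-only phase (default 1000).
#' @param init initial genotype.
#' @param seed optional RNG seed.
#' @return An `"evo_run"` object whose trajectory covers both phases, with
#'   a `phase` column (`"drift"` / `"coevolution"`).
#' @export
linkage_coevolution <- function(kin, params, drift_generations = 1000,
                                init = c(1, 1, 0, 0), seed = NULL) {
  .seed_if(seed)
  K <- as.numeric(calibrate_K(kin, params$alpha, verify = FALSE))
  pop <- cell_population(params$N, init, rho = 0.5, alpha = params$alpha)
  drift_params <- params
  drift_params$mu <- 0
  drift_params$max_generations <- as.integer(drift_generations)
  ## drift phase: run the full cap with an unsatisfiable criterion
  drift_params$convergence <- convergence_criterion(
    epsilon_s = .Machine$double.xmin, window = drift_generations + 1,
    report_window = params$convergence$report_window)
  phase1 <- run_to_steady_state(pop, kin, drift_params, K = K)
  crit <- params$convergence
  if (is.null(crit$epsilon_rho))
    crit <- convergence_criterion(epsilon_s = crit$epsilon_s,
                                  window = crit$window,
                                  epsilon_rho = crit$epsilon_s,
                                  report_window = crit$report_window)
  params$convergence <- crit
  phase2 <- run_to_steady_state(phase1$population, kin, params, K = K)
  tr1 <- phase1$trajectory
  tr2 <- phase2$trajectory
  tr1$phase <- "drift"
  tr2$phase <- "coevolution"
  tr2 <- tr2[-1L, ]                      # generation 0 of phase 2 repeats
  tr2$generation <- tr2$generation + max(tr1$generation)
  out <- phase2
  out$trajectory <- rbind(tr1, tr2)
  out
}

#' Assign cells to archetypal genotype classes
#'
#' Bins each cell to the nearest of the recurrent equilibrium genotypes
#' (symmetric producers, fully asymmetric sender/receiver types, and the
#' half-rate mixed types that arise under strong recombination) by
#' Euclidean distance in rate space, with an `"other"` class beyond the
#' given radius. Useful to summarize what a steady-state population
#' consists of.
#'
#' @param pop a [cell_population()] or a rates matrix.
#' @param radius maximum distance to an archetype (default 0.25).
#' @return A factor of archetype labels, one per cell.
#' @export
bin_genotypes <- function(pop, radius = 0.25) {
  rates <- if (inherits(pop, "cell_population")) pop$rates else pop
  arch <- rbind(
    "1100" = c(1, 1, 0, 0), "0011" = c(0, 0, 1, 1),
    "1001" = c(1, 0, 0, 1), "0110" = c(0, 1, 1, 0),
    "1_05_0_05" = c(1, 0.5, 0, 0.5), "0_05_1_05" = c(0, 0.5, 1, 0.5),
    "05_1_05_0" = c(0.5, 1, 0.5, 0), "05_0_05_1" = c(0.5, 0, 0.5, 1))
  d2 <- sapply(seq_len(nrow(arch)), function(k)
    rowSums(sweep(rates, 2, arch[k, ])^2))
  d2 <- matrix(d2, nrow = nrow(rates))
  nearest <- max.col(-d2, ties.method = "first")
  lab <- rownames(arch)[nearest]
  lab[sqrt(d2[cbind(seq_len(nrow(rates)), nearest)]) > radius] <- "other"
  factor(lab, levels = c(rownames(arch), "other"))
}

#' Threshold of the symmetric-to-asymmetric transition along a grid
#'
#' Given steady-state symmetry values along an increasing grid of a swept
#' parameter (typically the within-cell binding rate), returns the midpoint
#' between the last clearly symmetric point (`s* > 0.9`) and the first
#' clearly asymmetric point (`s* < 0.1`). `NA` if either side is absent.
#'
#' @param x increasing grid of the swept parameter.
#' @param s_star steady-state symmetry at each grid point.
#' @return Scalar threshold estimate or `NA`.
#' @export
transition_threshold <- function(x, s_star) {
  stopifnot(length(x) == length(s_star), !is.unsorted(x))
  hi <- which(s_star > 0.9)
  lo <- which(s_star < 0.1)
  if (!length(hi) || !length(lo)) return(NA_real_)
  last_hi <- max(hi)
  first_lo <- min(lo[lo > last_hi], Inf)
  if (!is.finite(first_lo)) return(NA_real_)
  (x[last_hi] + x[first_lo]) / 2
}
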
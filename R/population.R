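## Population containers and the mutation operators of the evolutionary
## model: a finite haploid population of N cells, each carrying a ligand
## locus (nu_L, nu_l), a receptor locus (nu_R, nu_r) and a recombination
## modifier allele rho in [0, 0.5].

#' Convergence criterion for evolutionary runs
#'
#' A run is considered at mutation-selection balance when the population
#' symmetry statistic `s` is stable: the range of `s` over the trailing
#' `window` generations is below `epsilon_s`, checked every `window`
#' generations. For runs in which the recombination modifier evolves,
#' stability of the population-mean modifier value is additionally required
#' (`epsilon_rho`). Reported steady-state values are averaged over the
#' trailing `report_window` generations.
#'
#' With recurrent mutation the statistic fluctuates above typical
#' thresholds, so such runs usually terminate at the generation cap; the
#' criterion mainly serves invasion experiments, where mutation is off and
#' `s` becomes exactly constant once genotype frequencies stop changing.
#'
#' @param epsilon_s stability threshold on `s` (default `1e-5`; invasion
#'   experiments use `1e-7`).
#' @param window generations per stability check (default 100).
#' @param epsilon_rho stability threshold on mean modifier value, or `NULL`
#'   to ignore the modifier (default).
#' @param report_window trailing generations averaged for reported values.
#' @return An object of class `"convergence_criterion"`.
#' @export
convergence_criterion <- function(epsilon_s = 1e-5, window = 100,
                                  epsilon_rho = NULL, report_window = 1000) {
  stopifnot(epsilon_s > 0, window >= 1,
            is.null(epsilon_rho) || epsilon_rho > 0, report_window >= 1)
  structure(list(epsilon_s = epsilon_s, window = as.integer(window),
                 epsilon_rho = epsilon_rho,
                 report_window = as.integer(report_window)),
            class = "convergence_criterion")
}

#' Parameters of the evolutionary model
#'
#' @param N population size (haploid cells).
#' @param M number of cells that mate per generation; must be even and
#'   `< N`. Defaults to `N / 2`. Each mated pair leaves two offspring, and
#'   the population is regulated back to `N` by sampling offspring with
#'   replacement.
#' @param mu per-gene mutation probability of the four production rates.
#' @param sigma standard deviation of the Gaussian mutation increment.
#' @param mu_rho mutation probability of the recombination modifier.
#' @param sigma_rho standard deviation of modifier mutation increments.
#' @param alpha production capacity per locus.
#' @param max_generations cap on run length (default `1e5`).
#' @param convergence a [convergence_criterion()].
#' @param mate_attempt_cap maximum number of pair draws per generation
#'   before the run aborts (an all-incompatible population cannot complete
#'   its matings and is not viable).
#' @param selection if `FALSE`, every sampled pair mates (`P = 1`),
#'   switching off selection; used for neutral-drift checks.
#' @return An object of class `"evolution_params"`.
#' @export
evolution_params <- function(N = 1000, M = N / 2, mu = 0.01, sigma = 0.1,
                             mu_rho = 0, sigma_rho = 0.1, alpha = 1,
                             max_generations = 1e5,
                             convergence = convergence_criterion(),
                             mate_attempt_cap = 1e8,
                             selection = TRUE) {
  N <- as.integer(N); M <- as.integer(M)
  stopifnot(N >= 2, M >= 2, M < N, M %% 2L == 0L,
            mu >= 0, mu <= 1, sigma >= 0, mu_rho >= 0, mu_rho <= 1,
            sigma_rho >= 0, alpha > 0, max_generations >= 1,
            inherits(convergence, "convergence_criterion"),
            mate_attempt_cap > 0, is.logical(selection))
  structure(list(N = N, M = M, mu = mu, sigma = sigma,
                 mu_rho = mu_rho, sigma_rho = sigma_rho, alpha = alpha,
                 max_generations = as.integer(max_generations),
                 convergence = convergence,
                 mate_attempt_cap = mate_attempt_cap,
                 selection = selection),
            class = "evolution_params")
}

#' Construct a population of cells
#'
#' @param n number of cells.
#' @param rates either a single [production_rates()] genotype (replicated),
#'   a length-4 numeric vector, or an `n x 4` matrix with columns
#'   `nu_L`, `nu_R`, `nu_l`, `nu_r`.
#' @param rho recombination-modifier allele(s) in `[0, 0.5]`, recycled to
#'   length `n`.
#' @param alpha locus capacity used for validation.
#' @return An object of class `"cell_population"`: a list with a rates
#'   matrix, modifier vector `rho`, `generation` counter and `alpha`.
#' @examples
#' pop <- cell_population(100, c(1, 1, 0, 0))
#' pop
#' @export
cell_population <- function(n, rates, rho = 0, alpha = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (inherits(rates, "production_rates")) {
    alpha <- attr(rates, "alpha")
    rates <- unclass(rates)
  }
  if (is.null(dim(rates))) {
    stopifnot(length(rates) == 4)
    rates <- matrix(rates, n, 4, byrow = TRUE)
  }
  stopifnot(is.matrix(rates), nrow(rates) == n, ncol(rates) == 4)
  colnames(rates) <- c("nu_L", "nu_R", "nu_l", "nu_r")
  apply(rates, 1, .check_rates, alpha = alpha)
  rho <- rep_len(rho, n)
  stopifnot(all(rho >= 0), all(rho <= 0.5))
  structure(list(rates = rates, rho = rho, generation = 0L, alpha = alpha),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("Population of %d cells (generation %d)\n",
              nrow(x$rates), x$generation))
  cat(sprintf("  symmetry s = %.4f, mean rho = %.4f\n",
              symmetry_statistic(x), mean(x$rho)))
  cat(sprintf("  mean rates: nu_L = %.3f, nu_R = %.3f, nu_l = %.3f, nu_r = %.3f\n",
              mean(x$rates[, 1]), mean(x$rates[, 2]),
              mean(x$rates[, 3]), mean(x$rates[, 4])))
  invisible(x)
}

#' Population symmetry statistic
#'
#' Measures how equally cells produce each ligand-receptor system's two
#' components: `s = 1 - (1 / 2N) * sum_i (|nu_L_i - nu_R_i| +
#' |nu_l_i - nu_r_i|)`. A population of symmetric producers has `s = 1`;
#' one of fully polarized sender/receiver types, such as equal numbers of
#' `(1,0,0,1)` and `(0,1,1,0)` cells, has `s = 0`.
#'
#' @param pop a [cell_population()].
#' @return Scalar `s` in `[0, 1]`.
#' @export
symmetry_statistic <- function(pop) {
  stopifnot(inherits(pop, "cell_population"))
  if (nrow(pop$rates) == 0L) stop("empty population", call. = FALSE)
  .symmetry(pop$rates)
}

.symmetry <- function(rates) {
  1 - (sum(abs(rates[, 1] - rates[, 2])) + sum(abs(rates[, 3] - rates[, 4]))) /
    (2 * nrow(rates))
}

## Deterministic mutation kernel: given a logical hit matrix and increments,
## apply the proposals, discard any that leave [0, alpha], then rescale each
## locus proportionally if its two rates exceed the capacity.
.mutate_rates <- function(rates, hits, eps, alpha) {
  prop <- rates
  prop[hits] <- prop[hits] + eps
  bad <- prop < 0 | prop > alpha
  prop[bad] <- rates[bad]
  sL <- prop[, 1] + prop[, 3]
  f <- ifelse(sL > alpha, alpha / sL, 1)
  prop[, 1] <- prop[, 1] * f
  prop[, 3] <- prop[, 3] * f
  sR <- prop[, 2] + prop[, 4]
  f <- ifelse(sR > alpha, alpha / sR, 1)
  prop[, 2] <- prop[, 2] * f
  prop[, 4] <- prop[, 4] * f
  prop
}

#' Mutate production rates of every cell
#'
#' Each of the four production-rate genes of each cell mutates independently
#' with probability `mu`, adding a `N(0, sigma)` increment. A proposal that
#' leaves `[0, alpha]` is discarded (the gene is unchanged). If a locus's
#' two rates then sum above `alpha`, both are rescaled proportionally so the
#' sum equals `alpha` exactly.
#'
#' @param pop a [cell_population()].
#' @param params an [evolution_params()].
#' @return The mutated population.
#' @export
mutate_production <- function(pop, params) {
  stopifnot(inherits(pop, "cell_population"), inherits(params, "evolution_params"))
  if (params$mu <= 0) return(pop)
  n <- nrow(pop$rates)
  hits <- matrix(stats::runif(4L * n) < params$mu, n, 4)
  if (any(hits)) {
    eps <- stats::rnorm(sum(hits), 0, params$sigma)
    pop$rates <- .mutate_rates(pop$rates, hits, eps, params$alpha)
  }
  pop
}

#' Mutate the recombination-modifier allele of every cell
#'
#' With probability `mu_rho` per cell, the modifier value receives a
#' `N(0, sigma_rho)` increment and is clamped to the admissible range
#' `[0, 0.5]` of a recombination probability.
#'
#' @inheritParams mutate_production
#' @return The mutated population.
#' @export
mutate_modifier <- function(pop, params) {
  stopifnot(inherits(pop, "cell_population"), inherits(params, "evolution_params"))
  if (params$mu_rho <= 0) return(pop)
  n <- length(pop$rho)
  hits <- stats::runif(n) < params$mu_rho
  if (any(hits)) {
    pop$rho[hits] <- pmin(pmax(pop$rho[hits] +
                                 stats::rnorm(sum(hits), 0, params$sigma_rho),
                               0), 0.5)
  }
  pop
}
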
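#' Kinetic parameters of ligand-receptor signaling
#'
#' Bundles the physical constants of the within-cell binding kinetics and of
#' the between-cell signaling interaction. Within a cell, free ligand L and
#' free receptor R associate at rate `k_on` and the complex dissociates at
#' rate `k_off`; free molecules and complex are degraded at rates `deg_L`,
#' `deg_R` and `deg_LR`. Between cells, `k_between` scales the affinity of a
#' sender's free ligand for a receiver's free receptor. `n_cost` is the
#' exponent of the self-signaling cost: for `n_cost = 0` self-bound complex
#' only depletes free molecules, for `n_cost >= 1` it additionally corrupts
#' the readout of the incoming signal. `K_sat` is the saturation constant of
#' the mating-probability function; it is usually left `NULL` and filled in
#' by [calibrate_K()].
#'
#' @param k_on within-cell binding rate (concentration^-1 time^-1), >= 0.
#' @param k_off within-cell unbinding rate (time^-1), >= 0.
#' @param k_between between-cell coupling; defaults to `k_on / k_off`, the
#'   within-cell affinity, when `k_off > 0`.
#' @param deg common degradation rate used for `deg_L`, `deg_R` and `deg_LR`
#'   unless these are given individually; must be > 0.
#' @param deg_L,deg_R,deg_LR degradation rates of free ligand, free receptor
#'   and bound complex (time^-1), each > 0.
#' @param n_cost self-signaling cost exponent, >= 0 (typically 0, 1 or 2).
#' @param K_sat saturation constant of the mating probability, > 0 or `NULL`.
#'
#' @return An object of class `"kinetic_params"`.
#' @examples
#' kin <- kinetic_params(k_on = 5, k_off = 1, deg = 0.1, n_cost = 1)
#' kin
#' @export
kinetic_params <- function(k_on = 1, k_off = 1,
                           k_between = if (k_off > 0) k_on / k_off else 1,
                           deg = 0.5,
                           deg_L = deg, deg_R = deg, deg_LR = deg,
                           n_cost = 1, K_sat = NULL) {
  stopifnot(is.numeric(k_on), length(k_on) == 1, k_on >= 0,
            is.numeric(k_off), length(k_off) == 1, k_off >= 0,
            is.numeric(k_between), length(k_between) == 1, k_between >= 0,
            is.numeric(n_cost), length(n_cost) == 1, n_cost >= 0)
  for (g in c(deg_L, deg_R, deg_LR)) {
    if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g <= 0)
      stop("degradation rates must be strictly positive", call. = FALSE)
  }
  if (!is.null(K_sat)) {
    if (!is.numeric(K_sat) || length(K_sat) != 1 || K_sat <= 0)
      stop("K_sat must be a single positive number", call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off, k_between = k_between,
                 deg_L = deg_L, deg_R = deg_R, deg_LR = deg_LR,
                 n_cost = n_cost, K_sat = K_sat),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters\n")
  cat(sprintf("  k_on = %g, k_off = %g, k_between = %g\n",
              x$k_on, x$k_off, x$k_between))
  cat(sprintf("  degradation: L = %g, R = %g, LR = %g\n",
              x$deg_L, x$deg_R, x$deg_LR))
  cat(sprintf("  self-signaling cost exponent n = %g\n", x$n_cost))
  cat(sprintf("  K_sat = %s\n",
              if (is.null(x$K_sat)) "<uncalibrated>" else format(x$K_sat)))
  invisible(x)
}

#' Production-rate genotype of a cell
#'
#' A cell carries two mutually incompatible ligand-receptor pairs, (L, R)
#' and (l, r). The ligand locus holds the production rates `nu_L` and
#' `nu_l`; the receptor locus holds `nu_R` and `nu_r`. Production capacity
#' is shared within each locus: `nu_L + nu_l <= alpha` and
#' `nu_R + nu_r <= alpha`.
#'
#' @param nu_L,nu_R,nu_l,nu_r production rates, each in `[0, alpha]`.
#' @param alpha production capacity per locus (default 1; > 1 models synergy
#'   between the two ligands or receptors, < 1 competition).
#' @return A named numeric vector of class `"production_rates"` with an
#'   `alpha` attribute.
#' @examples
#' production_rates(1, 1, 0, 0)       # symmetric signaler
#' production_rates(1, 0, 0, 1)       # fully asymmetric: sends L, receives r
#' @export
production_rates <- function(nu_L, nu_R, nu_l, nu_r, alpha = 1) {
  v <- c(nu_L = nu_L, nu_R = nu_R, nu_l = nu_l, nu_r = nu_r)
  .check_rates(v, alpha)
  structure(v, alpha = alpha, class = "production_rates")
}

.check_rates <- function(v, alpha, tol = 1e-9) {
  if (!is.numeric(v) || length(v) != 4 || any(!is.finite(v)))
    stop("production rates must be four finite numbers", call. = FALSE)
  if (any(v < -tol) || any(v > alpha + tol))
    stop("production rates must lie in [0, alpha]", call. = FALSE)
  if (v[1] + v[3] > alpha + tol)
    stop("ligand locus exceeds capacity: nu_L + nu_l > alpha", call. = FALSE)
  if (v[2] + v[4] > alpha + tol)
    stop("receptor locus exceeds capacity: nu_R + nu_r > alpha", call. = FALSE)
  invisible(v)
}

#' @export
print.production_rates <- function(x, ...) {
  cat(sprintf("Production rates (alpha = %g): nu_L = %g, nu_R = %g, nu_l = %g, nu_r = %g\n",
              attr(x, "alpha"), x[1], x[2], x[3], x[4]))
  invisible(x)
}

## Vectorized steady-state solver for one ligand-receptor pair.
##
## At equilibrium the complex satisfies a quadratic obtained by eliminating
## [LR] through the complex balance [LR] (k_off + deg_LR) = k_on [L][R] and
## substituting the flux balances nu_L = deg_L [L] + deg_LR [LR] and
## nu_R = deg_R [R] + deg_LR [LR]:
##   k_on deg_LR^2 B^2
##     - (k_on deg_LR (nu_L + nu_R) + (k_off + deg_LR) deg_L deg_R) B
##     + k_on nu_L nu_R = 0.
## The physical root is the smaller one, written as 2c / (-b + sqrt(b^2-4ac))
## for numerical stability (b < 0 always; the form yields B = 0 exactly when
## either production rate or k_on is zero). The larger root violates
## [L], [R] >= 0.
.solve_pair <- function(nu_L, nu_R, k_on, k_off, deg_L, deg_R, deg_LR) {
  a <- k_on * deg_LR^2
  b <- -(k_on * deg_LR * (nu_L + nu_R) + (k_off + deg_LR) * deg_L * deg_R)
  cc <- k_on * nu_L * nu_R
  disc <- pmax(b * b - 4 * a * cc, 0)
  B <- 2 * cc / (-b + sqrt(disc))
  L <- (nu_L - deg_LR * B) / deg_L
  R <- (nu_R - deg_LR * B) / deg_R
  list(L = pmax(L, 0), R = pmax(R, 0), B = B)
}

#' Steady state of one within-cell ligand-receptor pair
#'
#' Solves the mass-action kinetics of free ligand, free receptor and bound
#' complex in a single cell for their unique non-negative equilibrium. The
#' quadratic system is solved in closed form; the returned state satisfies
#' the flux balances `nu_ligand = deg_L * L_free + deg_LR * LR_bound` and
#' `nu_receptor = deg_R * R_free + deg_LR * LR_bound` to relative tolerance
#' 1e-9 (checked, and an error is raised otherwise: a violation signals a
#' pathological parameter set).
#'
#' @param nu_ligand,nu_receptor production rates of the pair, >= 0.
#' @param kin a [kinetic_params()] object.
#' @return An object of class `"pair_steady_state"`: a list with components
#'   `L_free`, `R_free` and `LR_bound`.
#' @examples
#' kin <- kinetic_params(k_on = 1, k_off = 1, deg = 0.5)
#' solve_pair_steady_state(1, 1, kin)
#' @export
solve_pair_steady_state <- function(nu_ligand, nu_receptor, kin) {
  stopifnot(inherits(kin, "kinetic_params"),
            is.numeric(nu_ligand), nu_ligand >= 0,
            is.numeric(nu_receptor), nu_receptor >= 0)
  s <- .solve_pair(nu_ligand, nu_receptor, kin$k_on, kin$k_off,
                   kin$deg_L, kin$deg_R, kin$deg_LR)
  if (any(s$L < -1e-9) || any(s$R < -1e-9) || any(s$B < -1e-9))
    stop("no non-negative steady state found; check kinetic parameters",
         call. = FALSE)
  ## flux-balance conservation check
  rel <- function(x, y) abs(x - y) / pmax(abs(y), 1e-12)
  bal_L <- rel(kin$deg_L * s$L + kin$deg_LR * s$B, nu_ligand)
  bal_R <- rel(kin$deg_R * s$R + kin$deg_LR * s$B, nu_receptor)
  if (any(bal_L > 1e-9 & nu_ligand > 0) || any(bal_R > 1e-9 & nu_receptor > 0))
    stop("steady-state flux balance violated; parameter pathology",
         call. = FALSE)
  structure(list(L_free = s$L, R_free = s$R, LR_bound = s$B),
            class = "pair_steady_state")
}

#' @export
print.pair_steady_state <- function(x, ...) {
  cat(sprintf("Pair steady state: [L]* = %g, [R]* = %g, [LR]* = %g\n",
              x$L_free, x$R_free, x$LR_bound))
  invisible(x)
}

#' Within-cell signal state for both ligand-receptor pairs
#'
#' Applies [solve_pair_steady_state()] to each of the two mutually
#' incompatible pairs, (L, R) from `nu_L`, `nu_R` and (l, r) from `nu_l`,
#' `nu_r`. There is no cross-binding between the two systems, so the pairs
#' are solved independently.
#'
#' @param g a [production_rates()] genotype.
#' @param kin a [kinetic_params()] object.
#' @return An object of class `"cell_signal_state"`: a list with components
#'   `pair_LR` and `pair_lr`, each a `"pair_steady_state"`.
#' @export
cell_signal_state <- function(g, kin) {
  stopifnot(inherits(g, "production_rates"))
  structure(list(pair_LR = solve_pair_steady_state(g[["nu_L"]], g[["nu_R"]], kin),
                 pair_lr = solve_pair_steady_state(g[["nu_l"]], g[["nu_r"]], kin)),
            class = "cell_signal_state")
}

#' @export
print.cell_signal_state <- function(x, ...) {
  cat("Cell signal state\n  (L,R): ")
  print(x$pair_LR)
  cat("  (l,r): ")
  print(x$pair_lr)
  invisible(x)
}
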
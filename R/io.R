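## Configuration loading/validation and tabular output writers for the
## command-line front end.

.known_experiments <- c("equilibrium", "invade", "grid", "sweep",
                        "linkage", "landscape")

.kin_keys <- c("k_on", "k_off", "k_between", "deg", "deg_L", "deg_R",
               "deg_LR", "n_cost")
.evo_keys <- c("N", "M", "mu", "sigma", "mu_rho", "sigma_rho", "alpha",
               "max_generations", "epsilon_s", "window", "epsilon_rho",
               "report_window", "mate_attempt_cap")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with blocks `experiment`,
#' `kinetics`, `evolution`, and optional top-level `seed`, `out_dir` and
#' `replicates`. Unknown keys anywhere are rejected; missing values fall
#' back to the package defaults (notably `M = N/2`, `k_between =
#' k_on/k_off`). The experiment block must name one of the supported
#' experiments and may carry experiment-specific options (e.g. `rho_fixed`,
#' `dx`, `dy`, `p`, `rho_grid`, `drift_generations`, `resident`, `family`).
#'
#' @param path path to a YAML or JSON file.
#' @return A validated object of class `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ## keep YAML-1.1 boolean-like scalars (notably the key "N") literal
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
    "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x))
  known_top <- c("experiment", "kinetics", "evolution", "seed", "out_dir",
                 "replicates", "log_level")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$experiment) || is.null(cfg$experiment$name))
    stop("configuration must contain an 'experiment' block with a 'name'",
         call. = FALSE)
  if (!cfg$experiment$name %in% .known_experiments)
    stop("unknown experiment name: ", cfg$experiment$name, call. = FALSE)

  kin_args <- cfg$kinetics %||% list()
  bad <- setdiff(names(kin_args), .kin_keys)
  if (length(bad))
    stop("unknown kinetics key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  kin <- do.call(kinetic_params, kin_args)

  evo_args <- cfg$evolution %||% list()
  bad <- setdiff(names(evo_args), .evo_keys)
  if (length(bad))
    stop("unknown evolution key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  crit_args <- evo_args[intersect(names(evo_args),
                                  c("epsilon_s", "window", "epsilon_rho",
                                    "report_window"))]
  evo_args <- evo_args[setdiff(names(evo_args), names(crit_args))]
  if (length(crit_args))
    evo_args$convergence <- do.call(convergence_criterion, crit_args)
  params <- do.call(evolution_params, evo_args)

  exp_known <- c("name", "rho_fixed", "init", "dx", "dy", "p", "rho_grid",
                 "drift_generations", "resident", "mutants", "family",
                 "grid_step")
  bad <- setdiff(names(cfg$experiment), exp_known)
  if (length(bad))
    stop("unknown experiment key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  structure(list(experiment = cfg$experiment, kin = kin, params = params,
                 seed = cfg$seed %||% NULL,
                 replicates = cfg$replicates %||% 1L,
                 out_dir = cfg$out_dir %||% "."),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Tiny polynomial rolling hash over the serialized configuration, for
## deterministic output file names (no hashing dependency needed). Modulus
## 2^29 keeps every intermediate exact in double precision.
.param_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 536870912
  sprintf("%08x", h)
}

#' Execute a run configuration and write its artifacts
#'
#' Dispatches to the experiment named in the configuration, then writes the
#' resulting tables as CSV and a metadata JSON (full parameter set, seed,
#' calibrated `K` and convergence reason) into `out_dir`. File names follow
#' `{experiment}_{param-hash}_{seed}`, so identical configurations map to
#' identical names and byte-identical outputs.
#'
#' @param config a [load_config()] result.
#' @param dry_run if `TRUE`, validate and return the resolved parameters
#'   without simulating.
#' @return Invisibly, a character vector of the files written (or the
#'   resolved configuration if `dry_run`).
#' @export
run_config <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dry_run) {
    print(config$kin)
    utils::str(config$params)
    return(invisible(config))
  }
  ex <- config$experiment
  kin <- config$kin
  params <- config$params
  seed <- config$seed
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ## hash only what determines the computation, not where it is written
  stem <- file.path(config$out_dir,
                    paste0(ex$name, "_",
                           .param_hash(list(ex, unclass(kin), unclass(params),
                                            seed, config$replicates)),
                           "_", seed %||% "noseed"))
  K <- as.numeric(calibrate_K(kin, params$alpha, verify = FALSE))
  files <- character(0)
  meta <- list(experiment = ex, seed = seed, K = K,
               kinetics = unclass(kin),
               evolution = unclass(params)[setdiff(names(unclass(params)),
                                                   "convergence")],
               convergence = unclass(params$convergence))

  write_tab <- function(df, suffix) {
    f <- paste0(stem, "_", suffix, ".csv")
    utils::write.csv(df, f, row.names = FALSE)
    f
  }

  if (ex$name == "equilibrium") {
    run <- equilibrium_experiment(kin, params,
                                  init = unlist(ex$init %||% c(1, 1, 0, 0)),
                                  rho_fixed = ex$rho_fixed %||% 0, seed = seed)
    files <- c(files, write_tab(run$trajectory, "trajectory"),
               write_tab(.snapshot_df(run$population), "snapshot"))
    meta$s_star <- run$s_star
    meta$converged <- run$converged
    meta$reason <- run$reason
  } else if (ex$name == "invade") {
    spec <- invasion_spec(unlist(ex$resident %||% c(1, 1, 0, 0)),
                          lapply(ex$mutants, unlist), p = ex$p %||% 0.01)
    res <- invasion_experiment(spec, kin, params,
                               rho_fixed = ex$rho_fixed %||% 0, seed = seed)
    files <- c(files, write_tab(res$run$trajectory, "trajectory"))
    meta$f_resident <- res$f_resident
    meta$f_mutants <- res$f_mutants
    meta$s_star <- res$s_star
  } else if (ex$name == "grid") {
    tab <- invasibility_grid(unlist(ex$dx), unlist(ex$dy), kin, params,
                             p = ex$p %||% 0.01,
                             replicates = config$replicates,
                             family = ex$family %||% "two_mutants",
                             rho_fixed = ex$rho_fixed %||% 0, seed = seed)
    files <- c(files, write_tab(tab, "grid"))
  } else if (ex$name == "sweep") {
    tab <- recombination_sweep(unlist(ex$rho_grid), kin, params,
                               replicates = config$replicates, seed = seed)
    files <- c(files, write_tab(tab, "sweep"))
  } else if (ex$name == "linkage") {
    run <- linkage_coevolution(kin, params,
                               drift_generations = ex$drift_generations %||% 1000,
                               seed = seed)
    files <- c(files, write_tab(run$trajectory, "trajectory"),
               write_tab(.snapshot_df(run$population), "snapshot"))
    meta$s_star <- run$s_star
    meta$rho_star <- run$rho_star
    meta$reason <- run$reason
  } else if (ex$name == "landscape") {
    res <- do.call(production_rates,
                   as.list(unlist(ex$resident %||% c(1, 1, 0, 0))))
    step <- ex$grid_step %||% 0.05
    lan <- invasion_landscape(res, kin, dx = seq(0, 1, by = step),
                              dy = seq(0, 1, by = step))
    f <- paste0(stem, "_landscape.csv")
    write_landscape(lan, f)
    files <- c(files, f, sub("\\.csv$", ".json", f))
  }

  mf <- paste0(stem, "_metadata.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(c(files, mf))
}

.snapshot_df <- function(pop) {
  data.frame(cell_id = seq_len(nrow(pop$rates)),
             nu_L = pop$rates[, 1], nu_R = pop$rates[, 2],
             nu_l = pop$rates[, 3], nu_r = pop$rates[, 4],
             rho = pop$rho)
}
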
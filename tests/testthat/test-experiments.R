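kin <- kinetic_params(k_on = 5, k_off = 1, deg = 0.5, n_cost = 1)

test_that("without mutation the equilibrium experiment is inert", {
  params <- tiny_params(N = 60, M = 30, mu = 0, max_generations = 300)
  run <- equilibrium_experiment(kin, params, seed = 3)
  expect_true(all(run$trajectory$s == 1))
  expect_true(run$converged)
  ## a fixed recombination rate is carried unchanged
  run <- equilibrium_experiment(kin, params, rho_fixed = 0.1, seed = 3)
  expect_true(all(run$trajectory$mean_rho == 0.1))
})

test_that("invasion bookkeeping: p = 0 and mutant-equals-resident cases", {
  params <- tiny_params(N = 60, M = 30, max_generations = 400)
  spec <- invasion_spec(c(1, 1, 0, 0), list(c(0, 1, 1, 0)), p = 0)
  res <- invasion_experiment(spec, kin, params, seed = 5)
  expect_equal(res$f_resident, 1)
  expect_equal(unname(res$f_mutants), 0)
  expect_equal(res$s_star, 1)
  ## a "mutant" identical to the resident leaves the population monomorphic
  spec <- invasion_spec(c(1, 1, 0, 0), list(c(1, 1, 0, 0)), p = 0.1)
  res <- invasion_experiment(spec, kin, params, seed = 5)
  expect_equal(res$f_resident, 1)
  expect_equal(res$s_star, 1)
})

test_that("invasion spec validates frequencies", {
  expect_error(invasion_spec(c(1, 1, 0, 0), list(c(0, 1, 1, 0)), p = 1))
  expect_error(invasion_spec(c(1, 1, 0, 0),
                             list(c(0, 1, 1, 0), c(1, 0, 0, 1)),
                             p = c(0.6, 0.6)))
})

test_that("the invasibility grid logs reproducible replicate seeds", {
  params <- tiny_params(N = 40, M = 20, max_generations = 150)
  tab <- invasibility_grid(dx = c(0, 1), dy = 0, kin, params,
                           replicates = 2, seed = 11, p = 0.05)
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("dx", "dy", "replicate", "seed", "s_star",
                      "f_resident", "f_mut1", "f_mut2"))
  expect_false(any(is.na(tab$seed)))
  ## dx = dy = 0: the mutants coincide with the resident, which persists
  expect_true(all(tab$f_resident[tab$dx == 0] == 1))
  ## any single cell of the heatmap can be reproduced in isolation
  ## (dx = 1, dy = 0: mutants (1-dx, 1, dx, 0) and (1, 1-dy, 0, dy))
  spec <- invasion_spec(c(1, 1, 0, 0),
                        list(c(0, 1, 1, 0), c(1, 1, 0, 0)), p = 0.05)
  redo <- invasion_experiment(spec, kin, params, seed = tab$seed[4])
  expect_equal(redo$s_star, tab$s_star[4])
})

test_that("the recombination sweep covers its grid deterministically", {
  params <- tiny_params(N = 40, M = 20, mu = 0, max_generations = 150)
  tab <- recombination_sweep(c(0, 0.25), kin, params, replicates = 2,
                             seed = 13)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$rho, c(0, 0, 0.25, 0.25))
  expect_true(all(tab$s_star == 1))   # no mutation: nothing evolves
})

test_that("linkage coevolution keeps phases and honors mu_rho = 0", {
  params <- tiny_params(N = 40, M = 20, mu = 0.05, mu_rho = 0,
                        max_generations = 100)
  run <- linkage_coevolution(kin, params, drift_generations = 50, seed = 17)
  expect_setequal(unique(run$trajectory$phase), c("drift", "coevolution"))
  ## modifier fixed at the maximal rate throughout
  expect_true(all(run$trajectory$mean_rho == 0.5))
  ## drift phase has production mutation off: s stays exactly 1
  expect_true(all(run$trajectory$s[run$trajectory$phase == "drift"] == 1))
  ## generations are contiguous across the phase boundary
  expect_equal(run$trajectory$generation, seq_len(nrow(run$trajectory)) - 1L)
})

test_that("genotype binning recognizes the archetypes", {
  rates <- rbind(c(1, 1, 0, 0), c(0.95, 0.05, 0.02, 0.9),
                 c(1, 0.5, 0, 0.5), c(0.5, 0.5, 0.5, 0.5))
  b <- bin_genotypes(rates)
  expect_equal(as.character(b[1:3]), c("1100", "1001", "1_05_0_05"))
  expect_equal(as.character(b[4]), "other")
  ## a larger radius assigns the midpoint genotype to its nearest archetype
  expect_equal(as.character(bin_genotypes(rates, radius = 1)[4]), "1_05_0_05")
})

test_that("transition-threshold extraction finds the midpoint", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(transition_threshold(x, c(0.99, 0.97, 0.95, 0.03, 0.02)), 3.5)
  expect_true(is.na(transition_threshold(x, c(1, 1, 1, 1, 1))))
  expect_true(is.na(transition_threshold(x, c(0, 0, 0, 0, 0))))
  expect_error(transition_threshold(c(2, 1), c(1, 0)))
})

test_that("substream seeds are deterministic and leave the RNG alone", {
  s1 <- substream_seeds(99, 5)
  s2 <- substream_seeds(99, 5)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 5L)
  set.seed(1)
  x <- runif(1)
  set.seed(1)
  invisible(substream_seeds(42, 3))
  expect_identical(runif(1), x)
  expect_true(all(is.na(substream_seeds(NULL, 3))))
})
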
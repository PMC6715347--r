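kin01 <- kinetic_params(k_on = 5, k_off = 1, deg = 0.1, n_cost = 1)

test_that("mating returns M/2 disjoint pairs of distinct cells", {
  pop <- cell_population(40, c(1, 1, 0, 0))
  params <- tiny_params(N = 40, M = 20)
  K <- as.numeric(calibrate_K(kin01, verify = FALSE))
  set.seed(3)
  mat <- sample_matings(pop, kin01, K, params)
  expect_equal(dim(mat$pairs), c(10L, 2L))
  ids <- as.vector(mat$pairs)
  expect_equal(length(unique(ids)), 20L)   # each cell mates at most once
  expect_true(all(mat$pairs[, 1] != mat$pairs[, 2]))
  expect_gte(mat$attempts, 10)
})

test_that("complementary asymmetric types only mate heterotypically", {
  rates <- rbind(matrix(rep(c(1, 0, 0, 1), each = 30), 30, 4),
                 matrix(rep(c(0, 1, 1, 0), each = 30), 30, 4))
  pop <- cell_population(60, rates)
  params <- tiny_params(N = 60, M = 30)
  K <- as.numeric(calibrate_K(kin01, verify = FALSE))
  set.seed(5)
  for (i in 1:30) {
    mat <- sample_matings(pop, kin01, K, params)
    type <- (mat$pairs > 30) + 0L
    expect_true(all(rowSums(type) == 1L))  # one cell of each type per pair
  }
})

test_that("acceptance rate in plain mode matches the mating probability", {
  ## monomorphic population: every valid draw is accepted with the same P,
  ## so the number of draws to the first mating is geometric with mean 1/P
  pop <- cell_population(20, c(1, 1, 0, 0))
  params <- tiny_params(N = 20, M = 2)
  st <- cell_signal_state(production_rates(1, 1, 0, 0), kin01)
  w <- incoming_signal(st, st, kin01)
  K <- 3 * w^2                           # gives P = 1/4 exactly
  P <- mating_probability(w, w, K)
  expect_equal(P, 0.25)
  set.seed(7)
  att <- replicate(400, sample_matings(pop, kin01, K, params,
                                       envelope = FALSE)$attempts)
  expect_equal(mean(att), 1 / P, tolerance = 0.15)
})

test_that("envelope acceleration leaves the pair distribution unchanged", {
  ## three genotype classes with unequal mating probabilities
  rates <- rbind(matrix(rep(c(1, 1, 0, 0), each = 20), 20, 4),
                 matrix(rep(c(0.8, 1, 0.2, 0), each = 20), 20, 4),
                 matrix(rep(c(1, 0.8, 0, 0.2), each = 20), 20, 4))
  pop <- cell_population(60, rates)
  params <- tiny_params(N = 60, M = 20)
  kin <- kinetic_params(k_on = 5, k_off = 1, deg = 0.5, n_cost = 1)
  K <- as.numeric(calibrate_K(kin, verify = FALSE))
  cls <- function(i) (i - 1L) %/% 20L + 1L
  count_types <- function(envelope, reps, seed) {
    set.seed(seed)
    out <- integer(6)
    for (r in seq_len(reps)) {
      mat <- sample_matings(pop, kin, K, params, envelope = envelope)
      a <- pmin(cls(mat$pairs[, 1]), cls(mat$pairs[, 2]))
      b <- pmax(cls(mat$pairs[, 1]), cls(mat$pairs[, 2]))
      key <- factor(paste0(a, b), levels = c("11", "12", "13", "22", "23", "33"))
      out <- out + table(key)
    }
    out
  }
  fast <- count_types(TRUE, reps = 150, seed = 11)
  slow <- count_types(FALSE, reps = 150, seed = 12)
  ## homogeneity of the two pair-type distributions
  chisq <- suppressWarnings(stats::chisq.test(rbind(fast, slow)))
  expect_gt(chisq$p.value, 0.01)
})

test_that("an all-incompatible population aborts with a diagnostic", {
  pop <- cell_population(20, c(1, 0, 0, 1))
  params <- tiny_params(N = 20, M = 10)
  K <- as.numeric(calibrate_K(kin01, verify = FALSE))
  expect_error(sample_matings(pop, kin01, K, params), "incompatible")
})

test_that("the attempt cap aborts rather than hanging", {
  ## one viable pair only, and a cap too small to find it reliably
  rates <- rbind(matrix(rep(c(1, 0, 0, 1), each = 19), 19, 4),
                 c(0, 1, 1, 0))
  pop <- cell_population(20, rates)
  params <- tiny_params(N = 20, M = 4, mate_attempt_cap = 50)
  K <- as.numeric(calibrate_K(kin01, verify = FALSE))
  set.seed(13)
  expect_error(sample_matings(pop, kin01, K, params), "cap")
})

test_that("regulation resamples offspring uniformly", {
  off <- cell_population(10, c(1, 1, 0, 0))
  out <- regulate(off, 25)
  expect_equal(nrow(out$rates), 25L)
  expect_true(all(out$rates[, 1] == 1))
  ## unbiasedness: tagged genotype frequency is preserved in expectation
  rates <- rbind(matrix(rep(c(1, 1, 0, 0), each = 30), 30, 4),
                 matrix(rep(c(0, 0, 1, 1), each = 70), 70, 4))
  off <- cell_population(100, rates)
  set.seed(17)
  freq <- replicate(600, mean(regulate(off, 100)$rates[, 1] == 1))
  se <- sd(freq) / sqrt(length(freq))
  expect_lt(abs(mean(freq) - 0.3), 3 * se + 1e-12)
  empty <- cell_population(1, c(1, 1, 0, 0))
  empty$rates <- empty$rates[0, , drop = FALSE]
  empty$rho <- numeric(0)
  expect_error(regulate(empty, 10), "empty")
})
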
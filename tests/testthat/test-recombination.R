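## Parents with distinct, recognizable loci so every offspring
## configuration can be classified.
p1 <- list(rates = c(nu_L = 1, nu_R = 0, nu_l = 0, nu_r = 1), rho = NA)
p2 <- list(rates = c(nu_L = 0, nu_R = 1, nu_l = 1, nu_r = 0), rho = NA)

## classify offspring 1 of a pair: which parent supplied its ligand locus
## and its modifier
classify <- function(off) {
  lig_from1 <- off$offspring1$rates[["nu_L"]] == 1
  mod_from1 <- off$offspring1$rho == 1
  if (lig_from1 && mod_from1) 1L        # R1-M1-L1 (no recombination)
  else if (lig_from1 && !mod_from1) 2L  # R1-M2-L1 (two events)
  else if (!lig_from1 && !mod_from1) 3L # R1-M2-L2 (one event)
  else 4L                               # R1-M1-L2 (one event)
}

test_that("rho = 0 transmits parental haplotypes unchanged", {
  a <- p1; a$rho <- 0
  b <- p2; b$rho <- 0
  set.seed(2)
  for (i in 1:20) {
    off <- recombine_pair(a, b)
    expect_equal(off$offspring1$rates, a$rates)
    expect_equal(off$offspring2$rates, b$rates)
  }
})

test_that("offspring configurations follow the exact multinomial law", {
  draws <- function(rho1, rho2, nrep) {
    a <- p1; a$rho <- rho1
    b <- p2; b$rho <- rho2
    vapply(seq_len(nrep), function(i) classify(recombine_pair(a, b)),
           integer(1))
  }
  set.seed(41)
  ## joint rate is the mean of the parental alleles: 0.1 and 0.3 give 0.2,
  ## so single-recombinant offspring (ligand locus crossed) arise with
  ## probability 2 rho (1 - rho)
  for (case in list(c(0.2, 0.2), c(0.1, 0.3))) {
    cfg <- draws(case[1], case[2], 2e4)
    rho <- mean(case)
    expect_equal(mean(cfg %in% 3:4), 2 * rho * (1 - rho), tolerance = 0.05)
  }
})

test_that("vectorized recombination matches the exact outcome table", {
  rates <- rbind(p1$rates, p2$rates)
  for (rho in c(0, 0.1, 0.25, 0.5)) {
    nrep <- 1e5
    set.seed(1000 + rho * 100)
    ## modifier alleles 1 and 0 label descent; joint rate is their mean,
    ## so draw configurations with both parents carrying allele `rho`
    ## via the internal kernel on cloned pairs
    pairs <- matrix(rep(c(1L, 2L), nrep), ncol = 2, byrow = TRUE)
    ## distinct modifier alleles (2 rho and 0, joint rate rho) label
    ## modifier descent; nu_L labels ligand-locus descent
    off2 <- gamsig:::.recombine(rates, c(2 * rho, 0), pairs)
    lig1 <- off2$rates[seq_len(nrep), "nu_L"] == 1
    mod1 <- off2$rho[seq_len(nrep)] == 2 * rho
    counts <- table(factor(paste0(as.integer(lig1), as.integer(mod1)),
                           levels = c("11", "10", "00", "01")))
    probs <- c((1 - rho)^2, rho^2, rho * (1 - rho), rho * (1 - rho))
    if (rho == 0) {
      expect_equal(as.integer(counts), c(nrep, 0L, 0L, 0L))
    } else {
      chisq <- suppressWarnings(stats::chisq.test(as.integer(counts),
                                                  p = probs))
      expect_gt(chisq$p.value, 0.01)
    }
    ## expected frequencies at rho = 0.2 are (0.64, 0.04, 0.16, 0.16)
    if (rho == 0.25) {
      expect_equal(as.numeric(counts) / nrep,
                   c(0.5625, 0.0625, 0.1875, 0.1875), tolerance = 0.05)
    }
  }
})

test_that("outcome frequencies at joint rate 0.2 match the exact law", {
  rates <- rbind(p1$rates, p2$rates)
  nrep <- 1e5
  set.seed(77)
  pairs <- matrix(rep(c(1L, 2L), nrep), ncol = 2, byrow = TRUE)
  off <- gamsig:::.recombine(rates, c(0.4, 0), pairs)   # joint rate 0.2
  lig1 <- off$rates[seq_len(nrep), "nu_L"] == 1
  mod1 <- off$rho[seq_len(nrep)] == 0.4
  freq <- c(mean(lig1 & mod1), mean(lig1 & !mod1),
            mean(!lig1 & !mod1), mean(!lig1 & mod1))
  expect_equal(freq, c(0.64, 0.04, 0.16, 0.16), tolerance = 0.02)
})

test_that("recombination shuffles but never creates haplotypes", {
  set.seed(43)
  for (i in 1:20) {
    a <- list(rates = unclass(random_genotype()), rho = runif(1, 0, 0.5))
    b <- list(rates = unclass(random_genotype()), rho = runif(1, 0, 0.5))
    off <- recombine_pair(a, b)
    lig <- function(x) paste(x$rates[c(1, 3)], collapse = "/")
    rec <- function(x) paste(x$rates[c(2, 4)], collapse = "/")
    expect_setequal(c(lig(off$offspring1), lig(off$offspring2)),
                    c(lig(a), lig(b)))
    expect_setequal(c(rec(off$offspring1), rec(off$offspring2)),
                    c(rec(a), rec(b)))
    expect_setequal(c(off$offspring1$rho, off$offspring2$rho),
                    c(a$rho, b$rho))
  }
})

test_that("free recombination makes all four configurations equally likely", {
  rates <- rbind(p1$rates, p2$rates)
  nrep <- 4e4
  set.seed(47)
  pairs <- matrix(rep(c(1L, 2L), nrep), ncol = 2, byrow = TRUE)
  off <- gamsig:::.recombine(rates, c(0.5, 0.5), pairs)
  lig1 <- off$rates[seq_len(nrep), "nu_L"] == 1
  expect_equal(mean(lig1), 0.5, tolerance = 0.02)
})
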
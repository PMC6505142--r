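test_that("additive simulator scales the QTL effect to the stated variance", {
  # MAF 0.5 QTL: population Var(z) = 2 * 0.5 * 0.5 = 0.5
  d <- make_haplotype_distribution(c(0.5, 0.5), pairwise_D = 0)
  G <- center_genotypes(sample_genotypes(d, 50000, seed = 41),
                        means = c(1, 1))
  y <- simulate_phenotype_additive(G[, 1], 0.01, var_z = 0.5)
  b <- attr(y, "true_params")$b
  expect_equal(b, sqrt(0.02), tolerance = 1e-12)
  # total variance 1 in expectation; 4 SE band at n = 50000
  expect_lt(abs(var(as.numeric(y)) - 1), 4 * sqrt(2 / 50000))
  expect_lt(abs(mean(y)), 2 * sd(y) / sqrt(length(y)))

  # a QTL explaining half of the phenotypic variance
  y5 <- simulate_phenotype_additive(G[, 1], 0.5, var_z = 0.5)
  expect_equal(attr(y5, "true_params")$b, sqrt(0.5 / 0.5), tolerance = 1e-12)
})

test_that("variance fraction outside (0,1) is rejected", {
  z <- rnorm(100)
  z <- z - mean(z)
  expect_error(simulate_phenotype_additive(z, 0), "strictly in")
  expect_error(simulate_phenotype_additive(z, 1), "strictly in")
  expect_error(simulate_phenotype_additive(z + 10, 0.1), "centered")
})

test_that("dominance simulator reduces to additive when d = 0", {
  d <- dist_generic()
  G <- center_genotypes(sample_genotypes(d, 5000, seed = 43))
  z <- G[, 1]
  b <- sqrt(0.01 / mean(z^2))
  ya <- simulate_phenotype_additive(z, 0.01, seed = 7)
  yd <- simulate_phenotype_dominance(z, a = b, d = 0,
                                     error_variance = 0.99, seed = 7)
  # same draws; the dominance path additionally centers the outcome
  expect_equal(as.numeric(yd), as.numeric(ya) - mean(ya), tolerance = 1e-12)
})

test_that("pure dominance variance matches HWE enumeration", {
  # z in {0,1,2} at MAF 0.5, centered: z - 1; y = z^2 + delta
  gfreq <- c(0.25, 0.5, 0.25)
  zc <- (0:2) - 1
  vz2 <- sum(gfreq * zc^4) - sum(gfreq * zc^2)^2   # Var(z^2) = 0.25
  d <- make_haplotype_distribution(c(0.5, 0.5), pairwise_D = 0)
  G <- center_genotypes(sample_genotypes(d, 50000, seed = 47),
                        means = c(1, 1))
  y <- simulate_phenotype_dominance(G[, 1], a = 0, d = 1, error_variance = 1)
  target <- vz2 + 1
  expect_lt(abs(var(as.numeric(y)) - target), 4 * target * sqrt(2 / 50000))
  expect_equal(mean(y), 0, tolerance = 1e-12)
})

test_that("multilocus simulator generalizes the additive one", {
  d <- dist_generic()
  G <- center_genotypes(sample_genotypes(d, 5000, seed = 53))
  y1 <- simulate_phenotype_additive(G[, 1], 0.01, seed = 13)
  ym <- simulate_phenotype_multilocus(G[, 1, drop = FALSE], 0.01, seed = 13)
  expect_equal(as.numeric(ym), as.numeric(y1), tolerance = 1e-12)
})

test_that("variance budget is enforced and bookkeeping holds", {
  d <- dist_generic()
  G <- center_genotypes(sample_genotypes(d, 50000, seed = 59))
  expect_error(
    simulate_phenotype_multilocus(G[, 1, drop = FALSE], 0.6,
                                  polygenic_fraction = 0.5),
    "budget")
  # heritability 0.5: main QTL 1%, infinitesimal 49%
  y <- simulate_phenotype_multilocus(G[, 1, drop = FALSE], 0.01,
                                     polygenic_fraction = 0.49, seed = 3)
  expect_equal(attr(y, "model_tag"), "multilocus+infinitesimal")
  expect_lt(abs(var(as.numeric(y)) - 1), 4 * sqrt(2 / 50000))
})

test_that("three QTLs can split the genetic variance equally", {
  d6 <- markov_haplotype_distribution(rep(0.3, 6), rho = rep(0.5, 5))
  G <- center_genotypes(sample_genotypes(d6, 20000, seed = 61))
  phis <- rep(0.01 / 3, 3)
  y <- simulate_phenotype_multilocus(G[, c(2, 4, 6)], phis, seed = 5)
  pars <- attr(y, "true_params")
  expect_equal(pars$variance_fractions, phis)
  expect_equal(pars$b, sqrt(phis / colMeans(G[, c(2, 4, 6)]^2)),
               tolerance = 1e-12)
  expect_lt(abs(var(as.numeric(y)) - 1), 4 * sqrt(2 / 20000))
})

test_that("polygenic term can be built from background loci", {
  d6 <- markov_haplotype_distribution(rep(0.3, 6), rho = rep(0.2, 5))
  G <- center_genotypes(sample_genotypes(d6, 10000, seed = 67))
  y <- simulate_phenotype_multilocus(G[, 1, drop = FALSE], 0.01,
                                     polygenic_fraction = 0.3,
                                     polygenic_source = G[, 3:6],
                                     seed = 71)
  expect_lt(abs(var(as.numeric(y)) - 1), 4 * sqrt(2 / 10000) + 0.02)
})
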
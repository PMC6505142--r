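test_that("linkage equilibrium empties the right-hand side", {
  m <- exact_moments(dist_le_qtl(), 1, c(2, 3))
  expect_equal(m$rhs_additive, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(m$rhs_dominance, c(0, 0, 0), tolerance = 1e-12)
})

test_that("an unlinked marker diagonalizes the coefficient matrix", {
  m <- exact_moments(dist_marker_indep(), 1, c(2, 3))
  expect_equal(m$T[1, 2], 0, tolerance = 1e-12)
  expect_equal(m$T[1, 3], 0, tolerance = 1e-12)
  expect_equal(m$T[2, 3], 0, tolerance = 1e-12)
  expect_equal(m$rhs_additive[3], 0, tolerance = 1e-12)  # E(z x1 x2)
})

test_that("enumeration agrees with the independent double-loop oracle", {
  for (d in list(dist_generic(), dist_wei(), dist_perfect_ld())) {
    m <- exact_moments(d, 1, c(2, 3))
    o <- oracle_moments(d, 1, 2, 3)
    expect_equal(m$T, o$T, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(m$rhs_additive, o$rhs_additive, tolerance = 1e-12)
    expect_equal(m$rhs_dominance, o$rhs_dominance, tolerance = 1e-12)
    expect_equal(m$var_z, o$var_z, tolerance = 1e-12)
  }
})

test_that("empirical moments converge to the exact ones", {
  d <- dist_generic()
  ex <- exact_moments(d, 1, c(2, 3))
  for (n in c(1e4, 1e6)) {
    G <- center_genotypes(sample_genotypes(d, n, seed = 101))
    em <- empirical_moments(G, 1, c(2, 3))
    expect_equal(em$source, "empirical")
    expect_equal(em$n, n)
    # crude scale for the MC error of fourth-order moment averages
    tol <- 5 * sqrt(10 / n)
    expect_lt(max(abs(em$T - ex$T)), tol)
    expect_lt(max(abs(em$rhs_additive - ex$rhs_additive)), tol)
  }
})

test_that("empirical moments refuse sloppy input", {
  d <- dist_generic()
  G <- sample_genotypes(d, 100, seed = 7)
  expect_error(empirical_moments(G, 1, c(2, 3)), "centered")
  Gc <- center_genotypes(G)
  expect_error(empirical_moments(Gc, 1, c(2, 2)), "distinct")
  Gc2 <- center_genotypes(genotype_matrix(cbind(unclass(G), 1L)))
  expect_error(empirical_moments(Gc2, 1, c(2, 4)), "monomorphic")
})

test_that("genotypic LD is twice the haploid LD under random mating", {
  set.seed(211)
  for (k in 1:8) {
    d <- random_feasible_dist()
    m <- exact_moments(d, 1, c(2, 3))
    expect_equal(m$rhs_additive[1], 2 * haploid_moment(d, c(1, 2)),
                 tolerance = 1e-12)
    expect_equal(m$rhs_additive[2], 2 * haploid_moment(d, c(1, 3)),
                 tolerance = 1e-12)
    expect_equal(m$T[1, 2], 2 * haploid_moment(d, c(2, 3)),
                 tolerance = 1e-12)
    expect_equal(m$rhs_additive[3], 2 * haploid_moment(d, c(1, 2, 3)),
                 tolerance = 1e-12)
  }
})

test_that("LD summaries report the documented quantities", {
  d <- make_haplotype_distribution(c(0.5, 0.5), pairwise_D = 0.25)
  s <- ld_summary(d, c(1, 2))
  expect_equal(unname(s$r_squared), 1, tolerance = 1e-12)
  expect_equal(unname(s$genotypic_covariances),
               2 * unname(s$haploid_D), tolerance = 1e-12)

  # MAF 0.5 pair with haploid correlation rho: genotypic R2 = rho^2,
  # verified against the empirical correlation of enumerated diplotypes
  rho <- 0.6
  d2 <- make_haplotype_distribution(c(0.5, 0.5), pairwise_D = rho * 0.25)
  s2 <- ld_summary(d2, c(1, 2))
  expect_equal(unname(s2$r_squared), rho^2, tolerance = 1e-12)
  o <- oracle_moments(make_haplotype_distribution(
    c(0.5, 0.5, 0.5), pairwise_D = c(rho * 0.25, 0, 0)), 1, 2, 3)
  expect_equal(o$rhs_additive[1] / sqrt(o$var_z * o$T[1, 1]),
               rho, tolerance = 1e-12)
})

test_that("QTL joint R2 detects perfect linear dependence", {
  m_perfect <- exact_moments(dist_perfect_ld(), 1, c(2, 3))
  s <- ld_summary(dist_perfect_ld(), c(1, 2, 3))
  expect_equal(s$qtl_r2_joint, 1, tolerance = 1e-12)
  m_gen <- exact_moments(dist_generic(), 1, c(2, 3))
  expect_lt(ld_summary(dist_generic(), c(1, 2, 3))$qtl_r2_joint, 1)
})

test_that("haploid quantities are refused for unphased genotypes", {
  d <- dist_generic()
  Gc <- center_genotypes(sample_genotypes(d, 200, seed = 3))
  s <- ld_summary(Gc, c(1, 2, 3))
  expect_null(s$haploid_D)
  expect_true(all(s$r_squared >= 0 & s$r_squared <= 1))
  G <- sample_genotypes(d, 200, seed = 3)
  expect_error(ld_summary(G, c(1, 2)), "center")
})
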
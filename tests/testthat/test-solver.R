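test_that("linkage equilibrium kills all three coefficients", {
  sol <- solve_population_coefficients(
    exact_moments(dist_le_qtl(), 1, c(2, 3)), b = 1)
  expect_false(sol$degenerate)
  expect_equal(unname(coef(sol)), c(0, 0, 0), tolerance = 1e-10)
})

test_that("perfect LD with the marker pair forces a zero interaction", {
  # QTL allele identical to x1: all signal lies in the markers' span
  m <- exact_moments(dist_perfect_ld(), 1, c(2, 3))
  sol <- solve_population_coefficients(m, b = 1)
  expect_equal(sol$beta12, 0, tolerance = 1e-10)
  expect_equal(sol$beta1, 1, tolerance = 1e-10)  # z = x1 exactly
  expect_equal(sol$beta2, 0, tolerance = 1e-10)
})

test_that("a marker independent of the QTL pair cannot interact", {
  m <- exact_moments(dist_marker_indep(), 1, c(2, 3))
  sol <- solve_population_coefficients(m, b = 1)
  expect_equal(sol$beta12, 0, tolerance = 1e-10)
  expect_gt(abs(sol$beta1), 0)
  expect_equal(sol$beta1, m$rhs_additive[1] / m$T[1, 1], tolerance = 1e-10)
})

test_that("the pinned mutually-dependent triple yields the frozen beta12", {
  # value frozen from the diplotype-enumeration oracle
  m <- exact_moments(dist_generic(), 1, c(2, 3))
  sol <- solve_population_coefficients(m, b = 1)
  expect_equal(sol$beta12, 0.067447639332623, tolerance = 1e-12)
  expect_equal(sol$beta1, 0.186652467163649, tolerance = 1e-12)
  expect_equal(sol$beta2, 0.159957401490948, tolerance = 1e-12)
  # third-row formula agrees with the dense solve
  expect_equal(sum(sol$t_row3 * m$rhs_additive), sol$beta12,
               tolerance = 1e-10)
})

test_that("coefficients are exactly linear in the QTL effect", {
  m <- exact_moments(dist_generic(), 1, c(2, 3))
  s1 <- solve_population_coefficients(m, b = 0.3)
  s2 <- solve_population_coefficients(m, b = 0.6)
  expect_equal(coef(s2), 2 * coef(s1), tolerance = 1e-12)
})

test_that("singular systems are flagged, with the perfect-LD zero rule", {
  # x2 duplicates x1 on every haplotype, z in imperfect LD: betas withheld
  f <- numeric(8)
  st <- haplotype_states(3)
  dup <- st[, 2] == st[, 3]
  base <- make_haplotype_distribution(c(0.5, 0.5), pairwise_D = 0.1)
  key2 <- apply(haplotype_states(2), 1, paste, collapse = "")
  for (i in which(dup)) {
    k <- paste(st[i, 1:2], collapse = "")
    f[i] <- base$frequencies[match(k, key2)]
  }
  d_dup <- haplotype_distribution(f, locus_labels = c("z", "x1", "x2"))
  sol <- solve_population_coefficients(exact_moments(d_dup, 1, c(2, 3)))
  expect_true(sol$degenerate)
  expect_true(is.na(sol$beta12))

  # all three loci identical: markers span z perfectly -> beta12 = 0
  f3 <- numeric(8); f3[1] <- 0.5; f3[8] <- 0.5
  d_all <- haplotype_distribution(f3, locus_labels = c("z", "x1", "x2"))
  sol3 <- solve_population_coefficients(exact_moments(d_all, 1, c(2, 3)))
  expect_true(sol3$degenerate)
  expect_equal(sol3$beta12, 0)
})

test_that("dominance solver reduces to the additive one when d = 0", {
  m <- exact_moments(dist_generic(), 1, c(2, 3))
  sa <- solve_population_coefficients(m, b = 0.7)
  sd <- solve_population_coefficients_dominance(m, a = 0.7, d = 0)
  expect_equal(coef(sd), coef(sa), tolerance = 1e-12)
})

test_that("dominance with an unlinked marker stays interaction-free", {
  m <- exact_moments(dist_marker_indep(), 1, c(2, 3))
  for (ad in list(c(1, 0), c(0, 1), c(1, 1), c(0.3, -0.7))) {
    sol <- solve_population_coefficients_dominance(m, a = ad[1], d = ad[2])
    expect_equal(sol$beta12, 0, tolerance = 1e-10)
  }
})

test_that("third-order-only LD generates dominance phantom epistasis", {
  # markers pairwise independent of everything, jointly dependent with z;
  # closed form: beta12 = d * 2 (1 - 2 p_z) D123 / T33
  m <- exact_moments(dist_wei(), 1, c(2, 3))
  sol <- solve_population_coefficients_dominance(m, a = 0, d = 1)
  expect_equal(sol$beta12, 2 * (1 - 2 * 0.3) * 0.05 / m$T[3, 3],
               tolerance = 1e-10)
  expect_equal(sol$beta12, 0.16, tolerance = 1e-10)
  # the additive route is live here too (E(z x1 x2) = 2 D123 != 0)
  sol_a <- solve_population_coefficients(m, b = 1)
  expect_gt(abs(sol_a$beta12), 0.05)
})

test_that("multilocus interaction coefficient is additive in the QTL", {
  d6 <- markov_haplotype_distribution(rep(0.2, 6),
                                      rho = c(0.7, 0.3, 0.6, 0.3, 0.7))
  qtl <- c(2, 4, 6); markers <- c(1, 5)
  mom <- lapply(qtl, function(q) exact_moments(d6, q, markers))
  b <- c(0.1, 0.2, 0.15)
  combined <- interaction_coefficient_multilocus(mom, b)
  parts <- vapply(seq_along(qtl), function(k)
    solve_population_coefficients(mom[[k]], b = b[k])$beta12, 0)
  expect_equal(combined, sum(parts), tolerance = 1e-12)
  expect_gt(abs(combined), 0)

  # q = 1 equals the single-QTL solver
  expect_equal(interaction_coefficient_multilocus(mom[1], b[1]),
               solve_population_coefficients(mom[[1]], b = b[1])$beta12,
               tolerance = 1e-12)

  # all QTL in LE with the marker pair: no phantom interaction
  d_le <- markov_haplotype_distribution(rep(0.2, 6), rho = rep(0, 5))
  mom_le <- lapply(qtl, function(q) exact_moments(d_le, q, markers))
  expect_equal(interaction_coefficient_multilocus(mom_le, b), 0,
               tolerance = 1e-12)

  # mismatched marker pairs are rejected
  bad <- c(mom[1:2], list(exact_moments(d6, 6, c(1, 3))))
  expect_error(interaction_coefficient_multilocus(bad, b),
               "marker")
})

test_that("necessary-condition reports match the analytic regimes", {
  r_le <- check_necessary_conditions(dist_le_qtl(), 1, c(2, 3))
  expect_false(any(r_le$qtl_marker_LD))
  expect_false(r_le$phantom_possible)

  r_p <- check_necessary_conditions(dist_perfect_ld(), 1, c(2, 3))
  expect_true(r_p$perfect_LD)
  expect_false(r_p$phantom_possible)

  r_mi <- check_necessary_conditions(dist_marker_indep(), 1, c(2, 3))
  expect_false(r_mi$mutual_three_locus_LD)
  expect_false(r_mi$phantom_possible)

  r_g <- check_necessary_conditions(dist_generic(), 1, c(2, 3))
  expect_true(r_g$phantom_possible)
  expect_gt(abs(solve_population_coefficients(
    exact_moments(dist_generic(), 1, c(2, 3)))$beta12), 0)

  r_w <- check_necessary_conditions(dist_wei(), 1, c(2, 3))
  expect_true(r_w$phantom_possible)
})

test_that("a nonzero interaction implies the necessary conditions", {
  set.seed(307)
  for (k in 1:15) {
    d <- random_feasible_dist()
    sol <- solve_population_coefficients(exact_moments(d, 1, c(2, 3)))
    if (!sol$degenerate && abs(sol$beta12) > 1e-8) {
      rep <- check_necessary_conditions(d, 1, c(2, 3), tol = 1e-10)
      expect_true(rep$phantom_possible)
    }
  }
})

test_that("population and large-sample OLS coefficients agree", {
  d <- dist_generic()
  m <- exact_moments(d, 1, c(2, 3))
  phi <- 0.01
  b <- sqrt(phi / m$var_z)
  sol <- solve_population_coefficients(m, b = b)
  n <- 200000
  set.seed(311)
  G <- center_genotypes(sample_genotypes(d, n),
                        means = 2 * allele_frequencies(d))
  y <- simulate_phenotype_additive(G[, 1], phi, var_z = m$var_z)
  fit <- fit_interaction_model(y, G[, 2], G[, 3])
  est <- coef(fit)[c("x1", "x2", "x1:x2")]
  se <- fit$standard_errors[c("x1", "x2", "x1:x2")]
  expect_true(all(abs(est - unname(coef(sol))) < 5 * se))
})
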
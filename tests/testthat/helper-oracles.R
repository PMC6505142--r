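# Independent brute-force oracles and pinned distributions used across
# the suite.  The oracle enumeration below is written as an explicit
# double loop over ordered diplotypes, deliberately sharing no code with
# the package internals it checks.

oracle_moments <- function(dist, zi, m1, m2) {
  H <- dist$states
  f <- dist$frequencies
  p <- colSums(f * H)
  acc <- numeric(13)
  for (i in seq_len(nrow(H))) {
    for (j in seq_len(nrow(H))) {
      w <- f[i] * f[j]
      g <- H[i, ] + H[j, ] - 2 * p
      z <- g[zi]; x1 <- g[m1]; x2 <- g[m2]
      acc <- acc + w * c(x1^2, x1 * x2, x1^2 * x2, x2^2, x1 * x2^2,
                         x1^2 * x2^2, z * x1, z * x2, z * x1 * x2,
                         z^2 * x1, z^2 * x2, z^2 * x1 * x2, z^2)
    }
  }
  T <- matrix(c(acc[1], acc[2], acc[3],
                acc[2], acc[4], acc[5],
                acc[3], acc[5], acc[6] - acc[2]^2), 3, 3, byrow = TRUE)
  list(T = T, rhs_additive = acc[7:9],
       rhs_dominance = c(acc[10], acc[11], acc[12] - acc[13] * acc[2]),
       var_z = acc[13])
}

# haploid central moment by direct summation (independent of the
# package's haploid_moment)
oracle_haploid_moment <- function(dist, loci) {
  H <- dist$states
  f <- dist$frequencies
  p <- colSums(f * H)
  tot <- 0
  for (i in seq_len(nrow(H))) {
    v <- 1
    for (j in loci) v <- v * (H[i, j] - p[j])
    tot <- tot + f[i] * v
  }
  tot
}

## pinned distributions --------------------------------------------------

# mutually dependent but imperfectly linked triple (z, x1, x2)
dist_generic <- function() {
  make_haplotype_distribution(c(0.5, 0.4, 0.3),
                              pairwise_D = c(0.05, 0.04, 0.03),
                              three_locus_D = 0.01,
                              locus_labels = c("z", "x1", "x2"))
}

# QTL in linkage equilibrium with two mutually dependent markers:
# p(z) p(x1, x2)
dist_le_qtl <- function() {
  make_haplotype_distribution(c(0.5, 0.5, 0.4),
                              pairwise_D = c(0, 0, 0.1),
                              three_locus_D = 0,
                              locus_labels = c("z", "x1", "x2"))
}

# QTL allele identical to the x1 allele on every haplotype (perfect LD),
# x2 in feasible imperfect LD with the pair
dist_perfect_ld <- function() {
  make_haplotype_distribution(c(0.5, 0.5, 0.4),
                              pairwise_D = c(0.25, 0.05, 0.05),
                              three_locus_D = 0,
                              locus_labels = c("z", "x1", "x2"))
}

# x2 independent of the (z, x1) pair: p(z, x1) p(x2)
dist_marker_indep <- function() {
  make_haplotype_distribution(c(0.5, 0.5, 0.3),
                              pairwise_D = c(0.1, 0, 0),
                              three_locus_D = 0,
                              locus_labels = c("z", "x1", "x2"))
}

# flanking markers pairwise independent of each other and of the QTL,
# yet the three loci are jointly dependent (third-order LD only)
dist_wei <- function() {
  make_haplotype_distribution(c(0.3, 0.5, 0.5),
                              pairwise_D = c(0, 0, 0),
                              three_locus_D = 0.05,
                              locus_labels = c("z", "x1", "x2"))
}

# rejection-sample a feasible random three-locus law with all D nonzero
random_feasible_dist <- function() {
  repeat {
    p <- stats::runif(3, 0.15, 0.85)
    D <- stats::runif(3, -0.05, 0.05)
    D3 <- stats::runif(1, -0.02, 0.02)
    d <- tryCatch(make_haplotype_distribution(p, pairwise_D = D,
                                              three_locus_D = D3),
                  error = function(e) NULL)
    if (!is.null(d)) return(d)
  }
}
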
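#' Diploid genotype matrices
#'
#' A `geno_matrix` is an `n x L` matrix of diploid allele counts, either
#' raw (integers 0/1/2, counting copies of the reference allele) or
#' centered (real deviations from the per-locus mean).  Centering
#' convention matters throughout the package: population-level
#' derivations center at twice the allele frequency, empirical pipelines
#' center at the observed column means.
#'
#' @param codes `n x L` numeric matrix.
#' @param centered logical; are the codes mean deviations?
#' @param sample_means the per-locus means subtracted (length `L`), when
#'   centered.
#' @param locus_labels,positions per-locus metadata.
#' @return A matrix of class `geno_matrix` carrying the metadata as
#'   attributes.
#' @export
genotype_matrix <- function(codes, centered = FALSE, sample_means = NULL,
                            locus_labels = NULL, positions = NULL) {
  codes <- as.matrix(codes)
  if (!centered) {
    if (any(is.na(codes)) || any(codes != round(codes)) ||
        any(codes < 0 | codes > 2))
      stop("raw genotype codes must be integers in {0, 1, 2}", call. = FALSE)
  }
  if (is.null(locus_labels))
    locus_labels <- colnames(codes) %||% paste0("L", seq_len(ncol(codes)))
  colnames(codes) <- locus_labels
  structure(codes,
            centered = centered,
            sample_means = sample_means,
            positions = positions,
            class = c("geno_matrix", class(codes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "centered"))) "centered" else "raw 0/1/2"))
  k <- min(nrow(x), 6L)
  print(utils::head(unclass(x)[seq_len(k), , drop = FALSE]))
  if (nrow(x) > k) cat("...", nrow(x) - k, "more rows\n")
  invisible(x)
}

is_centered <- function(G) isTRUE(attr(G, "centered"))

#' Center genotype codes
#'
#' Expresses allele counts as deviations from their means.  By default
#' the observed column means are used (the empirical convention);
#' supplying `means` (e.g. twice the population allele frequencies)
#' gives population centering, which is what the exact moment machinery
#' assumes.
#'
#' @param G a raw [genotype_matrix()].
#' @param means optional vector of per-locus means to subtract; default
#'   is the observed column means.
#' @return A centered `geno_matrix`.
#' @export
center_genotypes <- function(G, means = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is_centered(G)) stop("genotypes already centered", call. = FALSE)
  if (is.null(means)) means <- colMeans(G)
  if (length(means) != ncol(G))
    stop("`means` must have one entry per locus", call. = FALSE)
  X <- sweep(unclass(G), 2, means)
  genotype_matrix(X, centered = TRUE, sample_means = means,
                  locus_labels = colnames(G),
                  positions = attr(G, "positions"))
}

#' Sample random-mating diploid genotypes
#'
#' Each individual's genotype is the sum of two haplotypes drawn
#' independently from `dist` (random union of gametes, i.e.
#' Hardy-Weinberg and random mating).  Under this sampling scheme the
#' genotypic LD moments are exactly twice their haploid counterparts.
#'
#' @param dist a [haplotype_distribution()] object.
#' @param n number of individuals.
#' @param seed optional integer seed for reproducibility.
#' @return A raw [genotype_matrix()] with `n` rows.
#' @export
sample_genotypes <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "haplo_dist"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  H <- nrow(dist$states)
  i1 <- sample.int(H, n, replace = TRUE, prob = dist$frequencies)
  i2 <- sample.int(H, n, replace = TRUE, prob = dist$frequencies)
  codes <- dist$states[i1, , drop = FALSE] + dist$states[i2, , drop = FALSE]
  genotype_matrix(codes, locus_labels = dist$locus_labels,
                  positions = dist$positions)
}

#' Simulate genotypes along a mock chromosome with decaying LD
#'
#' Haplotypes are generated by a first-order Markov chain over the loci:
#' the haploid allele correlation between adjacent loci `j` and `j+1` is
#' `exp(-(pos[j+1] - pos[j]) / decay_lambda)`, so LD between any two loci
#' decays exponentially with their base-pair distance.  Diploid
#' genotypes are formed by random union of two independent haplotypes.
#' The default decay length of 0.3 Mb makes the pairwise genotypic R2
#' fall steeply within the first half megabase and reach essentially
#' zero between 1 and 2 Mb.
#'
#' @param n_loci number of loci.
#' @param positions strictly increasing base-pair coordinates.
#' @param maf per-locus counted-allele frequencies in (0, 0.5] (recycled).
#' @param decay_lambda LD decay length in base pairs (default `3e5`).
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return A raw [genotype_matrix()].  The attribute `"expected_r2"`
#'   holds a data frame with one row per locus pair giving the base-pair
#'   distance and the expected genotypic R2 implied by the chain (the
#'   squared product of intervening adjacent correlations), so
#'   experiments can bin results by expected LD.
#' @export
simulate_chromosome_haplotypes <- function(n_loci, positions, maf,
                                           decay_lambda = 3e5, n,
                                           seed = NULL) {
  stopifnot(n_loci >= 2, length(positions) == n_loci)
  if (any(diff(positions) <= 0))
    stop("`positions` must be strictly increasing", call. = FALSE)
  maf <- rep_len(maf, n_loci)
  if (any(maf <= 0 | maf > 0.5))
    stop("`maf` entries must lie in (0, 0.5]", call. = FALSE)
  if (decay_lambda < 0) stop("`decay_lambda` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  rho <- if (decay_lambda == 0) rep(0, n_loci - 1) else
    exp(-diff(positions) / decay_lambda)
  tr <- markov_transitions(maf, rho)

  draw_haps <- function(m) {
    Hp <- matrix(0L, m, n_loci)
    Hp[, 1] <- as.integer(stats::runif(m) < maf[1])
    for (j in 2:n_loci) {
      pj <- ifelse(Hp[, j - 1] == 1L, tr$p11[j - 1], tr$p10[j - 1])
      Hp[, j] <- as.integer(stats::runif(m) < pj)
    }
    Hp
  }
  codes <- draw_haps(n) + draw_haps(n)

  pairs <- utils::combn(n_loci, 2)
  cum <- c(0, cumsum(-log(pmax(rho, .Machine$double.xmin))))
  r <- exp(-(cum[pairs[2, ]] - cum[pairs[1, ]]))
  if (any(rho == 0)) {
    # a zero link breaks the chain: any pair straddling it is independent
    zero_after <- which(rho == 0)
    for (z in zero_after)
      r[pairs[1, ] <= z & pairs[2, ] > z] <- 0
  }
  exp_r2 <- data.frame(locus1 = pairs[1, ], locus2 = pairs[2, ],
                       distance_bp = positions[pairs[2, ]] -
                         positions[pairs[1, ]],
                       expected_r2 = r^2)
  G <- genotype_matrix(codes, positions = positions)
  attr(G, "expected_r2") <- exp_r2
  G
}
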
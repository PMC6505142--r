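#' Exact law of L-locus haplotypes
#'
#' A `haplo_dist` stores the exact population distribution of biallelic
#' haplotypes at `L` linked loci.  Every analytic quantity in the package
#' (allele frequencies, pairwise and three-locus D coefficients, genotypic
#' moments under random mating) is derived from this object by enumeration,
#' so it is the single source of truth for "population" values.
#'
#' Haplotypes are indexed by their bit pattern: row `i` of
#' [haplotype_states()] gives the allele (0/1, where 1 is the counted
#' reference allele) carried at each locus, with locus 1 varying fastest.
#'
#' @param frequencies numeric vector of length `2^L` with the population
#'   frequency of each haplotype, ordered as in [haplotype_states()].
#' @param locus_labels optional character vector of locus identifiers;
#'   defaults to `"L1" ... "LL"`.
#' @param positions optional numeric vector of strictly increasing
#'   base-pair coordinates.
#'
#' @return An object of class `haplo_dist` with components `n_loci`,
#'   `frequencies`, `states` (the bit-pattern matrix), `locus_labels` and
#'   `positions`.
#'
#' @details Frequencies must be nonnegative and sum to one (tolerance
#'   1e-12), and every locus must be polymorphic: a monomorphic locus has
#'   no variance, so none of the LD or regression machinery is defined
#'   for it.
#'
#' @seealso [make_haplotype_distribution()] for the closed-form two- and
#'   three-locus constructor, [markov_haplotype_distribution()] for
#'   chains of loci with distance-decaying LD.
#' @export
haplotype_distribution <- function(frequencies, locus_labels = NULL,
                                   positions = NULL) {
  L <- log2(length(frequencies))
  if (L < 2 || abs(L - round(L)) > 1e-9)
    stop("`frequencies` must have length 2^L for some L >= 2", call. = FALSE)
  L <- as.integer(round(L))
  if (any(frequencies < -1e-12))
    stop("haplotype frequencies must be nonnegative", call. = FALSE)
  frequencies <- pmax(frequencies, 0)
  if (abs(sum(frequencies) - 1) > 1e-12)
    stop("haplotype frequencies must sum to 1 (within 1e-12)", call. = FALSE)
  if (is.null(locus_labels)) locus_labels <- paste0("L", seq_len(L))
  if (length(locus_labels) != L)
    stop("`locus_labels` must have one entry per locus", call. = FALSE)
  if (!is.null(positions)) {
    if (length(positions) != L || any(diff(positions) <= 0))
      stop("`positions` must be strictly increasing, one per locus",
           call. = FALSE)
  }
  states <- haplotype_states(L)
  p <- as.numeric(crossprod(frequencies, states))
  if (any(p <= 0) || any(p >= 1)) {
    bad <- locus_labels[p <= 0 | p >= 1]
    stop("monomorphic locus (allele frequency 0 or 1): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_loci = L, frequencies = as.numeric(frequencies), states = states,
         locus_labels = locus_labels, positions = positions),
    class = "haplo_dist")
}

#' Haplotype bit patterns
#'
#' Enumerates the `2^L` haplotypes at `L` biallelic loci as a 0/1 matrix,
#' one row per haplotype, locus 1 varying fastest.
#'
#' @param L number of loci.
#' @return A `2^L` by `L` integer matrix.
#' @export
haplotype_states <- function(L) {
  m <- as.matrix(do.call(expand.grid, rep(list(0:1), L)))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

haplotype_keys <- function(dist) {
  apply(dist$states, 1, paste, collapse = "")
}

#' Per-locus allele frequencies of a haplotype distribution
#'
#' @param dist a [haplotype_distribution()] object.
#' @return Numeric vector of counted-allele frequencies, one per locus.
#' @export
allele_frequencies <- function(dist) {
  stopifnot(inherits(dist, "haplo_dist"))
  as.numeric(crossprod(dist$frequencies, dist$states))
}

#' Haploid central LD moment
#'
#' Computes the central moment `E[(h_j1 - p_j1)...(h_jk - p_jk)]` of the
#' haploid allele indicators at the requested loci: for two loci this is
#' the classical pairwise D coefficient, for three loci the three-locus D.
#'
#' @param dist a [haplotype_distribution()] object.
#' @param loci integer vector of locus indices (repeats allowed, so e.g.
#'   `c(1, 1, 2)` gives `E[c1^2 c2]`).
#' @return The central moment as a single number.
#' @export
haploid_moment <- function(dist, loci) {
  stopifnot(inherits(dist, "haplo_dist"))
  if (any(loci < 1 | loci > dist$n_loci))
    stop("locus index out of range", call. = FALSE)
  p <- allele_frequencies(dist)
  cc <- sweep(dist$states, 2, p)
  v <- rep(1, nrow(cc))
  for (j in loci) v <- v * cc[, j]
  sum(dist$frequencies * v)
}

#' Construct a two- or three-locus distribution from allele frequencies
#' and D coefficients
#'
#' Builds the unique haplotype distribution whose marginal allele
#' frequencies, pairwise haploid D coefficients (central second moments
#' of the allele indicators) and, for three loci, three-locus D (central
#' third moment) equal the requested values.  The construction expands
#' the joint probability mass in the orthogonal Bernoulli basis, so each
#' haplotype frequency is the product of its marginals plus D-correction
#' terms; the round trip (recomputing the D coefficients from the
#' returned frequencies) is exact to machine precision.
#'
#' @param allele_freqs vector of `L` counted-allele frequencies, `L` of
#'   2 or 3, each strictly inside (0, 1).
#' @param pairwise_D pairwise haploid D values: a single number when
#'   `L = 2`; for `L = 3` either a symmetric `3 x 3` matrix (diagonal
#'   ignored) or a length-3 vector `(D12, D13, D23)`.
#' @param three_locus_D the haploid three-locus D coefficient (ignored
#'   when `L = 2`).
#' @inheritParams haplotype_distribution
#'
#' @return A [haplotype_distribution()] object.
#'
#' @details Not every combination of marginals and D values corresponds
#'   to a probability distribution.  Infeasible requests (some haplotype
#'   frequency below zero) fail with an error naming the offending
#'   haplotype bit pattern.  For more than three loci there is no
#'   closed-form parameterization of this kind; supply the `2^L`
#'   frequencies directly to [haplotype_distribution()] or use
#'   [markov_haplotype_distribution()].
#'
#' @examples
#' # linkage equilibrium: all four haplotypes at p1*p2 products
#' make_haplotype_distribution(c(0.5, 0.5), pairwise_D = 0)
#'
#' # a mutually dependent triple
#' d <- make_haplotype_distribution(c(0.5, 0.4, 0.3),
#'                                  pairwise_D = c(0.05, 0.04, 0.03),
#'                                  three_locus_D = 0.01)
#' haploid_moment(d, c(1, 2, 3))  # recovers 0.01
#' @export
make_haplotype_distribution <- function(allele_freqs, pairwise_D = 0,
                                        three_locus_D = 0,
                                        locus_labels = NULL,
                                        positions = NULL) {
  L <- length(allele_freqs)
  if (L > 3)
    stop("closed-form constructor supports L = 2 or 3 loci only; ",
         "for more loci pass the 2^L frequencies to ",
         "haplotype_distribution() directly", call. = FALSE)
  if (L < 2) stop("need at least two loci", call. = FALSE)
  if (any(allele_freqs <= 0) || any(allele_freqs >= 1))
    stop("allele frequencies must be strictly inside (0, 1)", call. = FALSE)

  D <- matrix(0, L, L)
  if (L == 2) {
    if (length(pairwise_D) != 1)
      stop("for two loci `pairwise_D` is a single number", call. = FALSE)
    D[1, 2] <- D[2, 1] <- pairwise_D
  } else {
    if (is.matrix(pairwise_D)) {
      if (!isTRUE(all.equal(pairwise_D, t(pairwise_D))))
        stop("`pairwise_D` matrix must be symmetric", call. = FALSE)
      D <- pairwise_D
    } else if (length(pairwise_D) == 3) {
      D[1, 2] <- D[2, 1] <- pairwise_D[1]
      D[1, 3] <- D[3, 1] <- pairwise_D[2]
      D[2, 3] <- D[3, 2] <- pairwise_D[3]
    } else if (length(pairwise_D) == 1) {
      D[upper.tri(D)] <- pairwise_D
      D[lower.tri(D)] <- pairwise_D
    } else stop("`pairwise_D` must be a scalar, length-3 vector or 3x3 matrix",
                call. = FALSE)
  }

  states <- haplotype_states(L)
  p <- allele_freqs
  # orthogonal-basis expansion: sign eps_j = +1 for allele 1, -1 for allele 0
  marg <- sweep(states, 2, p, function(h, p) ifelse(h == 1, p, 1 - p))
  eps <- ifelse(states == 1, 1, -1)
  f <- apply(marg, 1, prod)
  if (L == 2) {
    f <- f + D[1, 2] * eps[, 1] * eps[, 2]
  } else {
    f <- f + D[1, 2] * eps[, 1] * eps[, 2] * marg[, 3] +
             D[1, 3] * eps[, 1] * eps[, 3] * marg[, 2] +
             D[2, 3] * eps[, 2] * eps[, 3] * marg[, 1] +
             three_locus_D * eps[, 1] * eps[, 2] * eps[, 3]
  }
  if (any(f < -1e-12)) {
    keys <- apply(states, 1, paste, collapse = "")
    bad <- keys[which.min(f)]
    stop(sprintf(paste0("infeasible D combination: haplotype %s would have ",
                        "frequency %.3g < 0"), bad, min(f)), call. = FALSE)
  }
  haplotype_distribution(pmax(f, 0), locus_labels = locus_labels,
                         positions = positions)
}

#' Exact haplotype distribution of a first-order Markov chain of loci
#'
#' Builds the full `2^L`-state law of haplotypes whose allele indicators
#' form a first-order Markov chain along the chromosome, with marginal
#' frequencies `p` and adjacent-locus haploid correlations `rho`.  LD
#' decays multiplicatively with the number of intervening steps, which is
#' how the package emulates distance-decaying LD along a chromosome
#' (correlation `exp(-distance / decay_lambda)` between neighbours).
#'
#' @param p vector of `L` counted-allele frequencies in (0, 1).
#' @param rho vector of `L - 1` adjacent haploid correlations in `[0, 1)`.
#'   Correlations infeasible for a pair of marginals are clamped to the
#'   feasible maximum with a warning.
#' @inheritParams haplotype_distribution
#' @return A [haplotype_distribution()] object (requires `L <= 12`).
#' @export
markov_haplotype_distribution <- function(p, rho, locus_labels = NULL,
                                          positions = NULL) {
  L <- length(p)
  stopifnot(length(rho) == L - 1)
  if (L > 12)
    stop("exact enumeration limited to L <= 12 loci", call. = FALSE)
  tr <- markov_transitions(p, rho)
  states <- haplotype_states(L)
  f <- ifelse(states[, 1] == 1, p[1], 1 - p[1])
  for (j in 2:L) {
    pj <- ifelse(states[, j - 1] == 1, tr$p11[j - 1], tr$p10[j - 1])
    f <- f * ifelse(states[, j] == 1, pj, 1 - pj)
  }
  haplotype_distribution(f, locus_labels = locus_labels,
                         positions = positions)
}

# Transition probabilities of the binary Markov chain with marginals p and
# adjacent correlations rho; clamps infeasible D with a warning.
markov_transitions <- function(p, rho) {
  L <- length(p)
  if (any(rho < 0 | rho >= 1))
    stop("adjacent correlations must lie in [0, 1)", call. = FALSE)
  p11 <- p10 <- numeric(L - 1)
  for (j in seq_len(L - 1)) {
    q1 <- 1 - p[j]; q2 <- 1 - p[j + 1]
    D <- rho[j] * sqrt(p[j] * q1 * p[j + 1] * q2)
    Dmax <- min(p[j] * q2, q1 * p[j + 1])
    if (D > Dmax + 1e-15) {
      warning(sprintf(paste0("adjacent correlation %.4f infeasible for ",
                             "marginals (%.3f, %.3f); clamped to %.4f"),
                      rho[j], p[j], p[j + 1],
                      Dmax / sqrt(p[j] * q1 * p[j + 1] * q2)))
      D <- Dmax
    }
    p11[j] <- p[j + 1] + D / p[j]
    p10[j] <- p[j + 1] - D / q1
  }
  list(p11 = p11, p10 = p10)
}

#' @export
print.haplo_dist <- function(x, ...) {
  cat(sprintf("Haplotype distribution: %d loci, %d haplotypes\n",
              x$n_loci, length(x$frequencies)))
  p <- allele_frequencies(x)
  cat("Allele frequencies:",
      paste(sprintf("%s=%.4g", x$locus_labels, p), collapse = ", "), "\n")
  if (x$n_loci <= 4) {
    keys <- haplotype_keys(x)
    df <- data.frame(haplotype = keys, frequency = round(x$frequencies, 6))
    print(df, row.names = FALSE)
  }
  if (!is.null(x$positions))
    cat("Positions (bp):", paste(format(x$positions), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / deserialize a haplotype distribution as JSON
#'
#' Haplotype frequencies are keyed by their allele bit string in locus
#' order (e.g. `"101"` = allele 1 at loci 1 and 3).
#'
#' @param dist a [haplotype_distribution()] object.
#' @param path file path.
#' @return `read_haplotype_distribution` returns a `haplo_dist`;
#'   `write_haplotype_distribution` returns `path` invisibly.
#' @export
write_haplotype_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "haplo_dist"))
  freq <- as.list(dist$frequencies)
  names(freq) <- haplotype_keys(dist)
  obj <- list(n_loci = dist$n_loci, locus_labels = dist$locus_labels,
              positions = dist$positions, frequencies = freq)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_haplotype_distribution
#' @export
read_haplotype_distribution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- obj$n_loci
  keys <- names(obj$frequencies)
  states <- haplotype_states(L)
  want <- apply(states, 1, paste, collapse = "")
  f <- as.numeric(obj$frequencies[match(want, keys)])
  if (anyNA(f)) stop("missing haplotype keys in ", path, call. = FALSE)
  haplotype_distribution(f, locus_labels = obj$locus_labels,
                         positions = obj$positions)
}
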
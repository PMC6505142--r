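#' Genotypic moments of the three-locus interaction system
#'
#' A `moment_set` collects every expectation entering the population
#' regression of a phenotype on two markers and their product: the 3x3
#' coefficient matrix `T` of the centered regressors `(x1, x2, x1 x2)`
#' and the right-hand-side vectors coupling them to the causal genotype
#' `z` (additive: `E(z x1), E(z x2), E(z x1 x2)`; dominance:
#' `E(z^2 x1), E(z^2 x2), Cov(z^2, x1 x2)`).
#'
#' The (3,3) entry of `T` is stored as `E(x1^2 x2^2) - E(x1 x2)^2`: the
#' interaction regressor `x1 x2` has nonzero mean even though the
#' markers are centered, and this entry is its variance about that mean
#' - exactly the quantity that an ordinary least squares fit with an
#' intercept uses.  Likewise `E(x1^2 x2) = Cov(x1, x1 x2)` and
#' `E(z x1 x2) = Cov(z, x1 x2)` because `E(x1) = E(z) = 0`, so the whole
#' system is the (intercept-adjusted) normal-equation system of the
#' interaction regression.  For the same reason the third dominance
#' entry is stored as `Cov(z^2, x1 x2) = E(z^2 x1 x2) - E(z^2) E(x1 x2)`:
#' `z^2` has a nonzero mean, and only the covariance form makes the
#' population system the limit of the intercept-including OLS fit when
#' the two markers are themselves in LD (the two forms agree whenever
#' `E(x1 x2) = 0`, the usual setting in which the dominance emergence
#' criterion is quoted).
#'
#' @name moment_set
#' @seealso [exact_moments()], [empirical_moments()],
#'   [solve_population_coefficients()]
NULL

new_moment_set <- function(T, rhs_additive, rhs_dominance, var_z, var_z2,
                           source, n = NA_integer_, loci = NULL) {
  dimnames(T) <- list(c("x1", "x2", "x1:x2"), c("x1", "x2", "x1:x2"))
  structure(list(T = T, rhs_additive = rhs_additive,
                 rhs_dominance = rhs_dominance,
                 var_z = var_z, var_z2 = var_z2,
                 source = source, n = n, loci = loci),
            class = "moment_set")
}

#' Exact genotypic moments by diplotype enumeration
#'
#' Computes every moment of the interaction system exactly from a
#' haplotype distribution by enumerating all `2^L x 2^L` ordered
#' diplotypes (64 for three loci), forming each diplotype's
#' population-centered genotype codes and accumulating probability-
#' weighted products.  There is no sampling error; this enumeration is
#' the canonical "population" computation against which empirical and
#' closed-form results are checked.
#'
#' @param dist a [haplotype_distribution()] object (at most 10 loci).
#' @param qtl_index index of the causal locus `z`.
#' @param marker_indices length-2 vector with the indices of `x1`, `x2`.
#' @return A `moment_set` with `source = "exact"`, including the
#'   dominance right-hand side and the variances of `z` and of `z^2`.
#' @export
exact_moments <- function(dist, qtl_index, marker_indices) {
  stopifnot(inherits(dist, "haplo_dist"))
  idx <- c(qtl_index, marker_indices)
  if (length(idx) != 3 || anyDuplicated(idx))
    stop("need three distinct locus indices", call. = FALSE)
  if (any(idx < 1 | idx > dist$n_loci))
    stop("locus index out of range", call. = FALSE)
  if (dist$n_loci > 10)
    stop("diplotype enumeration limited to 10 loci", call. = FALSE)

  p <- allele_frequencies(dist)
  C <- sweep(dist$states[, idx, drop = FALSE], 2, p[idx])
  H <- nrow(C)
  i <- rep(seq_len(H), H)
  j <- rep(seq_len(H), each = H)
  w <- dist$frequencies[i] * dist$frequencies[j]
  z  <- C[i, 1] + C[j, 1]
  x1 <- C[i, 2] + C[j, 2]
  x2 <- C[i, 3] + C[j, 3]
  E <- function(v) sum(w * v)

  T <- matrix(c(E(x1^2),      E(x1 * x2),   E(x1^2 * x2),
                E(x1 * x2),   E(x2^2),      E(x1 * x2^2),
                E(x1^2 * x2), E(x1 * x2^2), E(x1^2 * x2^2) - E(x1 * x2)^2),
              3, 3, byrow = TRUE)
  rhs_a <- c(E(z * x1), E(z * x2), E(z * x1 * x2))
  # third entry mean-adjusted: with a centered phenotype the dominance
  # signal couples to the regressors through Cov(z^2, .), and only the
  # interaction regressor x1 x2 has a nonzero mean
  rhs_d <- c(E(z^2 * x1), E(z^2 * x2),
             E(z^2 * x1 * x2) - E(z^2) * E(x1 * x2))
  new_moment_set(T, rhs_a, rhs_d,
                 var_z = E(z^2), var_z2 = E(z^4) - E(z^2)^2,
                 source = "exact",
                 loci = dist$locus_labels[idx])
}

#' Empirical genotypic moments from sampled genotypes
#'
#' Sample analogue of [exact_moments()]: every expectation is replaced
#' by the corresponding sample average over the rows of a centered
#' genotype matrix.  The input must be sample-centered already; silent
#' auto-centering is deliberately refused so that the centering
#' convention in force is always explicit in the calling code.
#'
#' @param G a centered [genotype_matrix()].
#' @param z_column column index of the causal locus.
#' @param marker_columns length-2 vector of marker column indices.
#' @return A `moment_set` with `source = "empirical"` and `n` recorded.
#' @export
empirical_moments <- function(G, z_column, marker_columns) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!is_centered(G))
    stop("genotypes must be centered first (see center_genotypes()); ",
         "auto-centering is not performed", call. = FALSE)
  idx <- c(z_column, marker_columns)
  if (length(idx) != 3 || anyDuplicated(idx))
    stop("need three distinct column indices", call. = FALSE)
  n <- nrow(G)
  if (n < 10) stop("need at least 10 individuals", call. = FALSE)
  z <- G[, z_column]; x1 <- G[, marker_columns[1]]
  x2 <- G[, marker_columns[2]]
  if (stats::var(z) == 0 || stats::var(x1) == 0 || stats::var(x2) == 0)
    stop("monomorphic (constant) column among the requested loci",
         call. = FALSE)
  E <- function(v) mean(v)
  T <- matrix(c(E(x1^2),      E(x1 * x2),   E(x1^2 * x2),
                E(x1 * x2),   E(x2^2),      E(x1 * x2^2),
                E(x1^2 * x2), E(x1 * x2^2), E(x1^2 * x2^2) - E(x1 * x2)^2),
              3, 3, byrow = TRUE)
  rhs_a <- c(E(z * x1), E(z * x2), E(z * x1 * x2))
  rhs_d <- c(E(z^2 * x1), E(z^2 * x2),
             E(z^2 * x1 * x2) - E(z^2) * E(x1 * x2))
  new_moment_set(T, rhs_a, rhs_d,
                 var_z = E(z^2), var_z2 = E(z^4) - E(z^2)^2,
                 source = "empirical", n = n,
                 loci = colnames(G)[idx])
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("Genotypic moment set (%s%s)\n", x$source,
              if (!is.na(x$n)) paste0(", n = ", x$n) else ""))
  if (!is.null(x$loci))
    cat("  loci (z, x1, x2):", paste(x$loci, collapse = ", "), "\n")
  cat("Coefficient matrix T:\n")
  print(round(x$T, 6))
  cat("Additive rhs  E(z x1), E(z x2), E(z x1 x2):",
      paste(signif(x$rhs_additive, 6), collapse = ", "), "\n")
  cat("Dominance rhs E(z2 x1), E(z2 x2), E(z2 x1 x2):",
      paste(signif(x$rhs_dominance, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Linkage-disequilibrium summary of loci
#'
#' For an exact haplotype distribution: haploid pairwise D, the
#' three-locus D (when three loci are given), genotypic covariances
#' (twice the haploid D under random mating), pairwise genotypic R2
#' (squared correlation of the diploid codes) and, for three loci, the
#' proportion of QTL-genotype variance explained by the population
#' regression of the first locus on the other two (`qtl_r2_joint`).
#'
#' For an empirical genotype matrix only genotype-level quantities are
#' available; haploid D requires phase and is refused.
#'
#' @param x a [haplotype_distribution()] or a centered
#'   [genotype_matrix()].
#' @param loci two or three locus indices; with three, the first is
#'   treated as the QTL.
#' @return A list of class `ld_summary`.
#' @export
ld_summary <- function(x, loci) {
  if (length(loci) < 2 || length(loci) > 3 || anyDuplicated(loci))
    stop("`loci` must name two or three distinct loci", call. = FALSE)
  UseMethod("ld_summary")
}

#' @export
ld_summary.haplo_dist <- function(x, loci) {
  p <- allele_frequencies(x)
  pairs <- utils::combn(loci, 2)
  hapD <- apply(pairs, 2, function(pr) haploid_moment(x, pr))
  names(hapD) <- apply(pairs, 2, function(pr)
    paste(x$locus_labels[pr], collapse = ":"))
  gcov <- 2 * hapD
  denom <- apply(pairs, 2, function(pr) prod(p[pr] * (1 - p[pr])))
  r2 <- hapD^2 / denom
  d3 <- if (length(loci) == 3) haploid_moment(x, loci) else NULL
  qtl_r2 <- NULL
  if (length(loci) == 3) {
    m <- exact_moments(x, loci[1], loci[2:3])
    qtl_r2 <- qtl_r2_joint(m)
  }
  structure(list(haploid_D = hapD, three_locus_D = d3,
                 genotypic_covariances = gcov, r_squared = r2,
                 qtl_r2_joint = qtl_r2, source = "exact"),
            class = "ld_summary")
}

#' @export
ld_summary.geno_matrix <- function(x, loci) {
  if (!is_centered(x))
    stop("center genotypes before computing empirical LD summaries",
         call. = FALSE)
  pairs <- utils::combn(loci, 2)
  labs <- apply(pairs, 2, function(pr)
    paste(colnames(x)[pr], collapse = ":"))
  gcov <- apply(pairs, 2, function(pr) stats::cov(x[, pr[1]], x[, pr[2]]))
  r2 <- apply(pairs, 2, function(pr)
    stats::cor(x[, pr[1]], x[, pr[2]])^2)
  names(gcov) <- names(r2) <- labs
  qtl_r2 <- NULL
  if (length(loci) == 3) {
    fit <- stats::lm.fit(cbind(1, x[, loci[2]], x[, loci[3]]), x[, loci[1]])
    z <- x[, loci[1]]
    qtl_r2 <- 1 - sum(fit$residuals^2) / sum((z - mean(z))^2)
  }
  structure(list(haploid_D = NULL, three_locus_D = NULL,
                 genotypic_covariances = gcov, r_squared = r2,
                 qtl_r2_joint = qtl_r2, source = "empirical"),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat("LD summary (", x$source, ")\n", sep = "")
  if (!is.null(x$haploid_D)) {
    cat("  haploid D:",
        paste(sprintf("%s=%.5g", names(x$haploid_D), x$haploid_D),
              collapse = ", "), "\n")
    if (!is.null(x$three_locus_D))
      cat("  three-locus D:", signif(x$three_locus_D, 6), "\n")
  }
  cat("  genotypic covariance:",
      paste(sprintf("%s=%.5g", names(x$genotypic_covariances),
                    x$genotypic_covariances), collapse = ", "), "\n")
  cat("  R-squared:",
      paste(sprintf("%s=%.5g", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  if (!is.null(x$qtl_r2_joint))
    cat("  QTL variance explained by marker pair:",
        signif(x$qtl_r2_joint, 6), "\n")
  invisible(x)
}

# Proportion of Var(z) explained by the population regression of z on
# (x1, x2); uses a pseudo-inverse so perfectly collinear marker pairs
# (e.g. duplicated markers) are still handled.
qtl_r2_joint <- function(moments) {
  T2 <- moments$T[1:2, 1:2]
  rhs <- moments$rhs_additive[1:2]
  sv <- svd(T2)
  pos <- sv$d > max(sv$d) * 1e-12
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
  as.numeric(crossprod(rhs, beta)) / moments$var_z
}
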
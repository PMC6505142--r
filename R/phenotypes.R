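#' Simulate an additive single-QTL phenotype
#'
#' Generates `y = z * b + delta` where `z` is the centered QTL genotype,
#' `b = sqrt(phi / Var(z))` scales the allele-substitution effect so that
#' the QTL explains the fraction `phi` of a unit phenotypic variance, and
#' `delta ~ N(0, 1 - phi)`.  The expected total variance of `y` is 1.
#'
#' @param z centered QTL genotype column (numeric vector, mean ~ 0).
#' @param qtl_variance_fraction `phi`, the fraction of phenotypic
#'   variance explained by the QTL; strictly inside (0, 1).
#' @param seed optional integer seed.
#' @param var_z variance of `z` used to scale the effect.  Default is
#'   the observed (sample) variance of the supplied column; pass the
#'   population value (e.g. `2 p (1 - p)` for a locus with allele
#'   frequency `p`) to reproduce analytic calculations exactly.
#' @return A numeric vector of class `phenotype_vector` with attributes
#'   `model_tag = "additive"` and `true_params = list(b, phi, var_z)`.
#' @export
simulate_phenotype_additive <- function(z, qtl_variance_fraction,
                                        seed = NULL, var_z = NULL) {
  phi <- qtl_variance_fraction
  if (phi <= 0 || phi >= 1)
    stop("`qtl_variance_fraction` must lie strictly in (0, 1)", call. = FALSE)
  check_centered_column(z, "z")
  if (is.null(var_z)) var_z <- mean(z^2)
  if (var_z <= 0) stop("Var(z) must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  b <- sqrt(phi / var_z)
  y <- z * b + stats::rnorm(length(z), 0, sqrt(1 - phi))
  phenotype_vector(y, "additive", list(b = b, phi = phi, var_z = var_z))
}

#' Simulate a phenotype with dominance at the causal locus
#'
#' Generates `y = a z + d z^2 + delta`, `delta ~ N(0, error_variance)`,
#' then mean-centers `y`.  The squared genotype is used as-is (it is not
#' centered before entering the model); centering the phenotype absorbs
#' its mean.
#'
#' @param z centered QTL genotype column.
#' @param a additive value (effect of the linear genotype contrast).
#' @param d dominance value (effect of the squared genotype contrast).
#' @param error_variance residual variance, strictly positive.
#' @param seed optional integer seed.
#' @return A `phenotype_vector` with `model_tag = "dominance"`.
#' @export
simulate_phenotype_dominance <- function(z, a, d, error_variance = 1,
                                         seed = NULL) {
  if (error_variance <= 0)
    stop("`error_variance` must be positive", call. = FALSE)
  check_centered_column(z, "z")
  if (!is.null(seed)) set.seed(seed)
  y <- a * z + d * z^2 +
    stats::rnorm(length(z), 0, sqrt(error_variance))
  y <- y - mean(y)
  phenotype_vector(y, "dominance",
                   list(a = a, d = d, error_variance = error_variance))
}

#' Simulate a multi-QTL phenotype with optional polygenic background
#'
#' Generates `y = sum_j z_j b_j + u + delta` where each QTL effect is
#' scaled as in [simulate_phenotype_additive()] to explain its stated
#' variance fraction, `u` is an optional infinitesimal (polygenic) term
#' and the residual variance tops the total up to 1.
#'
#' The infinitesimal term is built, when `polygenic_source` is given, as
#' an equally weighted sum of the standardized background-locus codes,
#' rescaled to the requested variance share — many small effects of
#' equal size on the standardized scale.  Without a source matrix it is
#' an independent normal deviate with the same variance.
#'
#' @param Z `n x q` matrix of centered QTL genotype columns.
#' @param variance_fractions vector of `q` per-QTL variance fractions.
#' @param polygenic_fraction variance share of the infinitesimal term
#'   (default 0).
#' @param polygenic_source optional centered [genotype_matrix()] of
#'   background loci from which to build the infinitesimal term.
#' @param seed optional integer seed.
#' @param var_z optional vector of population variances for the QTL
#'   columns (default: observed column variances).
#' @return A `phenotype_vector` with `model_tag = "multilocus"` or
#'   `"multilocus+infinitesimal"`.
#' @export
simulate_phenotype_multilocus <- function(Z, variance_fractions,
                                          polygenic_fraction = 0,
                                          polygenic_source = NULL,
                                          seed = NULL, var_z = NULL) {
  Z <- as.matrix(Z)
  q <- ncol(Z)
  if (length(variance_fractions) != q)
    stop("`variance_fractions` must have one entry per QTL column",
         call. = FALSE)
  if (any(variance_fractions <= 0))
    stop("variance fractions must be positive", call. = FALSE)
  budget <- sum(variance_fractions) + polygenic_fraction
  if (budget >= 1)
    stop("variance budget (QTL fractions + polygenic fraction) must be < 1",
         call. = FALSE)
  for (j in seq_len(q)) check_centered_column(Z[, j], paste0("Z[,", j, "]"))
  if (is.null(var_z)) var_z <- colMeans(Z^2)
  if (!is.null(seed)) set.seed(seed)

  b <- sqrt(variance_fractions / var_z)
  g <- as.numeric(Z %*% b)

  u <- 0
  tag <- "multilocus"
  if (polygenic_fraction > 0) {
    tag <- "multilocus+infinitesimal"
    if (!is.null(polygenic_source)) {
      B <- unclass(polygenic_source)
      if (!is_centered(polygenic_source))
        B <- sweep(B, 2, colMeans(B))
      sdv <- sqrt(colMeans(B^2))
      keep <- sdv > 0
      u <- rowSums(sweep(B[, keep, drop = FALSE], 2, sdv[keep], "/"))
      su <- stats::sd(u)
      if (su == 0)
        stop("polygenic source has no variance", call. = FALSE)
      u <- u * sqrt(polygenic_fraction) / su
    } else {
      u <- stats::rnorm(nrow(Z), 0, sqrt(polygenic_fraction))
    }
  }

  y <- g + u + stats::rnorm(nrow(Z), 0, sqrt(1 - budget))
  phenotype_vector(y, tag,
                   list(b = b, variance_fractions = variance_fractions,
                        polygenic_fraction = polygenic_fraction,
                        var_z = var_z))
}

phenotype_vector <- function(values, model_tag, true_params) {
  structure(as.numeric(values), model_tag = model_tag,
            true_params = true_params, class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("Phenotype vector: n = %d, model = %s\n",
              length(x), attr(x, "model_tag")))
  cat(sprintf("  mean %.4g, variance %.4g\n", mean(x), stats::var(x)))
  invisible(x)
}

check_centered_column <- function(z, name) {
  if (!is.numeric(z)) stop("`", name, "` must be numeric", call. = FALSE)
  se <- stats::sd(z) / sqrt(length(z))
  if (length(z) > 1 && abs(mean(z)) > 4 * se + 1e-8)
    stop("`", name, "` does not look centered (mean = ",
         signif(mean(z), 3), "); center genotypes first", call. = FALSE)
  invisible(TRUE)
}
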
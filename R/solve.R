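#' Population coefficients of the marker-interaction regression
#'
#' Solves the population normal-equation system of the instrumental
#' regression `y ~ x1 + x2 + x1:x2` for its coefficients
#' `(beta1, beta2, beta12)`, given the genotypic moments and the
#' allele-substitution effect `b` of the untyped causal locus.  Under a
#' purely additive trait the coefficients are `T^{-1} rhs * b`, where
#' `T` is the moment matrix of the regressors and `rhs` couples them to
#' the causal genotype, so a nonzero `beta12` here is "phantom"
#' epistasis: an interaction coefficient created entirely by multi-locus
#' LD, with no interaction in the generating model.
#'
#' `beta12` is additionally recomputed from the explicit third-row
#' formula `beta12 = (t31 E(z x1) + t32 E(z x2) + t33 E(z x1 x2)) b`,
#' with `t3.` the third row of `T^{-1}`, and the two routes are required
#' to agree to 1e-10.
#'
#' Degenerate systems (rank-deficient `T`, e.g. a duplicated marker)
#' are detected by singular-value decomposition at relative tolerance
#' `tol`.  When the causal genotype is a perfect linear function of the
#' marker pair (`qtl_r2_joint = 1`), the linear span of the markers
#' carries the whole signal and the interaction coefficient is zero;
#' that value is reported with `degenerate = TRUE`.  A singular system
#' without that structure has no well-defined coefficients and all
#' betas are withheld (`NA`).
#'
#' @param moments a [exact_moments()] / [empirical_moments()] result.
#' @param b allele-substitution effect of the causal locus (default 1;
#'   all coefficients are exactly linear in `b`).
#' @param tol relative rank tolerance for the SVD (default 1e-10).
#' @return An object of class `phantom_coef` with fields `beta1`,
#'   `beta2`, `beta12`, `t_row3` (third row of `T^{-1}`, `NA` when
#'   degenerate), `degenerate`, `qtl_effect_scale` and `qtl_r2_joint`.
#' @export
solve_population_coefficients <- function(moments, b = 1, tol = 1e-10) {
  stopifnot(inherits(moments, "moment_set"))
  solve_coef_system(moments, moments$rhs_additive * b,
                    qtl_effect_scale = c(b = b), tol = tol,
                    perfect_ld_rule = TRUE)
}

#' Population coefficients under dominance at the causal locus
#'
#' Same system as [solve_population_coefficients()], but for a causal
#' model `y = a z + d z^2 + delta`: the right-hand side becomes
#' `a * rhs_additive + d * rhs_dominance`, so both additive and
#' dominance values can contribute to the phantom interaction.
#'
#' @inheritParams solve_population_coefficients
#' @param a additive value at the causal locus.
#' @param d dominance value at the causal locus.
#' @return A `phantom_coef` object with `qtl_effect_scale = c(a, d)`.
#' @export
solve_population_coefficients_dominance <- function(moments, a, d,
                                                    tol = 1e-10) {
  stopifnot(inherits(moments, "moment_set"))
  if (is.null(moments$rhs_dominance))
    stop("moment set lacks the dominance right-hand side", call. = FALSE)
  rhs <- a * moments$rhs_additive + d * moments$rhs_dominance
  solve_coef_system(moments, rhs, qtl_effect_scale = c(a = a, d = d),
                    tol = tol, perfect_ld_rule = (d == 0))
}

solve_coef_system <- function(moments, rhs, qtl_effect_scale, tol,
                              perfect_ld_rule) {
  T <- moments$T
  sv <- svd(T)
  rank <- sum(sv$d > max(sv$d) * tol)
  r2j <- qtl_r2_joint(moments)
  if (rank < 3L) {
    if (perfect_ld_rule && r2j >= 1 - 1e-8) {
      # causal genotype linearly spanned by the markers: no residual QTL
      # signal for the interaction contrast to absorb
      return(phantom_coef(NA_real_, NA_real_, 0, t_row3 = rep(NA_real_, 3),
                          degenerate = TRUE,
                          qtl_effect_scale = qtl_effect_scale,
                          qtl_r2_joint = r2j, moments = moments))
    }
    return(phantom_coef(NA_real_, NA_real_, NA_real_,
                        t_row3 = rep(NA_real_, 3), degenerate = TRUE,
                        qtl_effect_scale = qtl_effect_scale,
                        qtl_r2_joint = r2j, moments = moments))
  }
  beta <- unname(solve(T, rhs))
  Tinv <- solve(T)
  t_row3 <- unname(Tinv[3, ])
  beta12_t <- sum(t_row3 * rhs)
  if (abs(beta12_t - beta[3]) > 1e-10 * max(1, abs(beta[3])))
    stop("internal inconsistency: linear solve and third-row formula ",
         "disagree on beta12", call. = FALSE)
  phantom_coef(beta[1], beta[2], beta[3], t_row3 = t_row3,
               degenerate = FALSE, qtl_effect_scale = qtl_effect_scale,
               qtl_r2_joint = r2j, moments = moments)
}

phantom_coef <- function(beta1, beta2, beta12, t_row3, degenerate,
                         qtl_effect_scale, qtl_r2_joint, moments) {
  structure(list(beta1 = beta1, beta2 = beta2, beta12 = beta12,
                 t_row3 = t_row3, degenerate = degenerate,
                 qtl_effect_scale = qtl_effect_scale,
                 qtl_r2_joint = qtl_r2_joint, moments = moments),
            class = "phantom_coef")
}

#' @export
print.phantom_coef <- function(x, ...) {
  cat("Population coefficients of the marker-interaction regression\n")
  cat(sprintf("  beta1 = %s, beta2 = %s, beta12 = %s\n",
              signif(x$beta1, 6), signif(x$beta2, 6), signif(x$beta12, 6)))
  cat(sprintf("  causal effect scale: %s\n",
              paste(sprintf("%s = %g", names(x$qtl_effect_scale),
                            x$qtl_effect_scale), collapse = ", ")))
  cat(sprintf("  QTL variance explained by markers: %.6g\n", x$qtl_r2_joint))
  if (x$degenerate)
    cat("  [degenerate system: moment matrix numerically singular]\n")
  invisible(x)
}

#' @export
coef.phantom_coef <- function(object, ...) {
  c(beta1 = object$beta1, beta2 = object$beta2, beta12 = object$beta12)
}

#' Phantom interaction coefficient under a multi-QTL architecture
#'
#' For an additive multi-QTL trait `y = sum_j z_j b_j + delta` tested
#' with the same marker pair, the interaction right-hand side is the
#' effect-weighted sum of the per-QTL right-hand sides, so the combined
#' interaction coefficient is the third component of
#' `T^{-1} sum_j b_j rhs_j` - exactly linear in each `b_j`.
#'
#' @param per_qtl_moments list of `moment_set`s, one per QTL, all
#'   computed against the same marker pair.
#' @param effects vector of allele-substitution effects `b_j`.
#' @param T optional shared moment matrix; defaults to the (identical)
#'   matrix of the supplied moment sets.
#' @param tol relative rank tolerance.
#' @return The combined `beta12` (a single number).
#' @export
interaction_coefficient_multilocus <- function(per_qtl_moments, effects,
                                               T = NULL, tol = 1e-10) {
  stopifnot(is.list(per_qtl_moments),
            length(per_qtl_moments) == length(effects))
  marker_ids <- lapply(per_qtl_moments, function(m) m$loci[2:3])
  if (length(unique(vapply(marker_ids, paste, "", collapse = ":"))) > 1)
    stop("moment sets were computed against different marker pairs",
         call. = FALSE)
  Ts <- lapply(per_qtl_moments, `[[`, "T")
  if (is.null(T)) T <- Ts[[1]]
  for (Tk in Ts)
    if (max(abs(Tk - T)) > 1e-8 * max(1, max(abs(T))))
      stop("moment sets do not share the same marker moment matrix",
           call. = FALSE)
  rhs <- Reduce(`+`, Map(function(m, b) b * m$rhs_additive,
                         per_qtl_moments, as.list(effects)))
  sv <- svd(T)
  if (sum(sv$d > max(sv$d) * tol) < 3L)
    stop("marker moment matrix is singular", call. = FALSE)
  as.numeric(solve(T, rhs)[3])
}

#' Check the necessary conditions for phantom epistasis
#'
#' Phantom epistasis between two markers requires that the three loci
#' (causal locus and both markers) be in mutual but imperfect LD.
#' Concretely: (1) the causal locus must be in LD with at least one
#' marker (otherwise the whole right-hand side of the population system
#' vanishes); (2) the LD must be imperfect - if the causal genotype is
#' an exact linear function of the marker pair, the markers' linear
#' span captures all the signal and the interaction coefficient is
#' zero; (3) the three loci must be jointly in LD - if any one locus is
#' independent of the pair formed by the other two, the three-locus
#' moment factorizes and the interaction coefficient vanishes.
#'
#' Condition (3) is operationalized on the haploid law: locus `A` is
#' independent of the pair `(B, C)` iff the central moments
#' `D_AB`, `D_AC` and `D_ABC` are all zero (at tolerance `tol`).
#'
#' @param dist a [haplotype_distribution()] object.
#' @param qtl_index index of the causal locus.
#' @param marker_indices indices of the two markers.
#' @param tol numeric tolerance for "zero" (default 1e-10).
#' @return A list of class `condition_report` with per-condition
#'   booleans, the conjunction `phantom_possible`, and the numeric
#'   moments backing each decision.
#' @export
check_necessary_conditions <- function(dist, qtl_index, marker_indices,
                                       tol = 1e-10) {
  m <- exact_moments(dist, qtl_index, marker_indices)
  z <- qtl_index; m1 <- marker_indices[1]; m2 <- marker_indices[2]
  D <- c(z_x1 = haploid_moment(dist, c(z, m1)),
         z_x2 = haploid_moment(dist, c(z, m2)),
         x1_x2 = haploid_moment(dist, c(m1, m2)),
         z_x1_x2 = haploid_moment(dist, c(z, m1, m2)))

  qtl_marker_LD <- abs(m$rhs_additive) > tol
  names(qtl_marker_LD) <- c("E(z x1)", "E(z x2)", "E(z x1 x2)")
  cond1 <- any(qtl_marker_LD)

  r2j <- qtl_r2_joint(m)
  perfect_LD <- r2j >= 1 - tol
  cond2 <- !perfect_LD

  factorizes <- c(
    x2_indep = all(abs(D[c("z_x2", "x1_x2", "z_x1_x2")]) <= tol),
    x1_indep = all(abs(D[c("z_x1", "x1_x2", "z_x1_x2")]) <= tol),
    z_indep  = all(abs(D[c("z_x1", "z_x2", "z_x1_x2")]) <= tol))
  cond3 <- !any(factorizes)

  structure(list(qtl_marker_LD = qtl_marker_LD,
                 perfect_LD = perfect_LD,
                 mutual_three_locus_LD = cond3,
                 factorizations = factorizes,
                 phantom_possible = cond1 && cond2 && cond3,
                 qtl_r2_joint = r2j,
                 haploid_D = D,
                 rhs_additive = m$rhs_additive,
                 tol = tol),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  yn <- function(b) if (b) "yes" else "no"
  cat("Necessary conditions for phantom epistasis\n")
  cat(sprintf("  1. QTL in LD with a marker:        %s\n",
              yn(any(x$qtl_marker_LD))))
  cat(sprintf("  2. LD with marker pair imperfect:  %s  (QTL R2 = %.6g)\n",
              yn(!x$perfect_LD), x$qtl_r2_joint))
  cat(sprintf("  3. Three loci jointly in LD:       %s\n",
              yn(x$mutual_three_locus_LD)))
  cat(sprintf("  => phantom epistasis possible:     %s\n",
              yn(x$phantom_possible)))
  invisible(x)
}

#' Write a coefficient solution or condition report as JSON
#'
#' @param x a `phantom_coef` or `condition_report` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  obj <- unclass(x)
  obj$moments <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
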
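#' Fit the marker-interaction regression by ordinary least squares
#'
#' Fits `y = mu + x1 beta1 + x2 beta2 + (x1 x2) beta12 + C gamma + e`
#' where `x1`, `x2` are centered marker genotype columns and `C` an
#' optional matrix of covariates (e.g. principal components of the
#' genotype matrix, supplied as a generic matrix).  The interaction
#' regressor is the elementwise product of the centered markers and is
#' not re-centered: its nonzero mean is absorbed by the intercept, which
#' keeps the fitted interaction coefficient aligned with the population
#' system solved by [solve_population_coefficients()].
#'
#' Classical (homoskedastic) standard errors
#' `sigma_hat^2 (X'X)^{-1}` with `sigma_hat^2 = RSS / (n - p)` are the
#' default, matching standard GWAS interaction-test practice;
#' heteroskedasticity-robust (HC0 sandwich) errors are available via
#' `se_type = "hc0"`.
#'
#' @param y phenotype vector.
#' @param x1,x2 centered marker columns.
#' @param covariates optional `n x c` numeric matrix.
#' @param se_type `"classical"` (default) or `"hc0"`.
#' @return An object of class `phantom_fit` with coefficient estimates,
#'   standard errors, residual variance, residual degrees of freedom and
#'   the model frame dimensions.  Supports `coef()`, `vcov()`,
#'   `summary()`, `residuals()`, `fitted()` and `predict()`.
#' @examples
#' set.seed(1)
#' x1 <- rbinom(500, 2, 0.5) - 1; x2 <- rbinom(500, 2, 0.3) - 0.6
#' y <- 1 + 2 * x1 - x2 + 0.5 * x1 * x2 + rnorm(500, 0, 0.1)
#' fit <- fit_interaction_model(y, x1, x2)
#' coef(fit)
#' @export
fit_interaction_model <- function(y, x1, x2, covariates = NULL,
                                  se_type = c("classical", "hc0")) {
  se_type <- match.arg(se_type)
  y <- as.numeric(y)
  n <- length(y)
  if (length(x1) != n || length(x2) != n)
    stop("`y`, `x1` and `x2` must have equal length", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, `x1:x2` = x1 * x2)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("`covariates` must have one row per observation", call. = FALSE)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  vc <- if (se_type == "classical") sigma2 * XtXinv else
    XtXinv %*% crossprod(X * res) %*% XtXinv
  est <- fit$coefficients[colnames(X)]
  structure(list(estimates = est,
                 standard_errors = sqrt(diag(vc)),
                 vcov = vc,
                 residual_variance = sigma2,
                 residuals = res,
                 fitted_values = y - res,
                 n = n, p = p, df = df, se_type = se_type),
            class = "phantom_fit")
}

#' @export
coef.phantom_fit <- function(object, ...) object$estimates

#' @export
vcov.phantom_fit <- function(object, ...) object$vcov

#' @export
residuals.phantom_fit <- function(object, ...) object$residuals

#' @export
fitted.phantom_fit <- function(object, ...) object$fitted_values

#' @export
predict.phantom_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  x1 <- newdata$x1; x2 <- newdata$x2
  X <- cbind(1, x1, x2, x1 * x2)
  est <- object$estimates
  pred <- X %*% est[1:4]
  if (object$p > 4) {
    cv <- as.matrix(newdata$covariates)
    pred <- pred + cv %*% est[5:object$p]
  }
  as.numeric(pred)
}

#' @export
print.phantom_fit <- function(x, ...) {
  cat(sprintf("Marker-interaction OLS fit (n = %d, p = %d, %s SEs)\n",
              x$n, x$p, x$se_type))
  out <- data.frame(estimate = x$estimates, std_error = x$standard_errors)
  print(signif(out, 5))
  cat(sprintf("Residual variance: %.5g on %d df\n",
              x$residual_variance, x$df))
  invisible(x)
}

#' @export
summary.phantom_fit <- function(object, ...) {
  tval <- object$estimates / object$standard_errors
  tab <- cbind(Estimate = object$estimates,
               `Std. Error` = object$standard_errors,
               `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(-abs(tval), object$df))
  structure(list(coefficients = tab, residual_variance =
                   object$residual_variance, n = object$n, df = object$df),
            class = "summary.phantom_fit")
}

#' @export
print.summary.phantom_fit <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Residual variance %.5g on %d df (n = %d)\n",
              x$residual_variance, x$df, x$n))
  invisible(x)
}

#' Wald test of the marker-interaction coefficient
#'
#' Tests `H0: beta12 = 0` with the t statistic
#' `beta12_hat / SE(beta12_hat)` referred to a t distribution with
#' `n - p` degrees of freedom (indistinguishable from the normal
#' reference at GWAS-scale n).  Two-sided.
#'
#' @param fit a [fit_interaction_model()] result.
#' @param alpha significance level (default 0.05).
#' @return An object of class `phantom_test` with fields `statistic`,
#'   `p_value`, `df`, `alpha` and `reject`.
#' @export
wald_interaction_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "phantom_fit"))
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  se <- fit$standard_errors["x1:x2"]
  if (!is.finite(se) || se == 0)
    stop("degenerate fit: interaction standard error is zero", call. = FALSE)
  stat <- unname(fit$estimates["x1:x2"] / se)
  p <- 2 * stats::pt(-abs(stat), fit$df)
  structure(list(statistic = stat, p_value = p, df = fit$df,
                 alpha = alpha, reject = p < alpha,
                 estimate = unname(fit$estimates["x1:x2"]),
                 std_error = unname(se)),
            class = "phantom_test")
}

#' @export
print.phantom_test <- function(x, ...) {
  cat("Wald test of H0: beta12 = 0\n")
  cat(sprintf("  beta12_hat = %.5g (SE %.5g), t = %.4g, df = %d\n",
              x$estimate, x$std_error, x$statistic, x$df))
  cat(sprintf("  two-sided p = %.4g; %s at alpha = %g\n", x$p_value,
              if (x$reject) "rejected" else "not rejected", x$alpha))
  invisible(x)
}
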
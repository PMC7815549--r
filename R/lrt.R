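#' Likelihood-ratio test of nested variance-component models
#'
#' `chi2 = -2 * (LL_reduced - LL_full)` referred to a central chi-square on
#' the parameter-count difference.  When a single variance component is
#' dropped the null value lies on the boundary of the parameter space and
#' the central chi-square p-value is conservative; `mixture = TRUE` uses the
#' 50:50 mixture of chi-square(0) and chi-square(1) instead.
#'
#' @param full,reduced Either `pedvar_fit` objects (the reduced model's
#'   components must be a subset of the full model's) or bare log-likelihood
#'   values.
#' @param df Difference in parameter count; required when raw
#'   log-likelihoods are given, otherwise derived from the fits.
#' @param mixture Use the 50:50 boundary mixture p-value when `df == 1`.
#' @return A list `chi2`, `df`, `p`.
#' @examples
#' lr_test(-11422.35, -11444.53, df = 1)$chi2   # 44.36
#' @export
lr_test <- function(full, reduced, df = NULL, mixture = FALSE) {
  if (inherits(full, "pedvar_fit") && inherits(reduced, "pedvar_fit")) {
    if (!all(reduced$components %in% full$components))
      stop("reduced model components are not nested in the full model")
    if (is.null(df)) df <- full$np - reduced$np
    ll_f <- full$loglik; ll_r <- reduced$loglik
  } else {
    ll_f <- as.numeric(full); ll_r <- as.numeric(reduced)
    if (is.null(df)) stop("df required when comparing raw log-likelihoods")
  }
  chi2 <- -2 * (ll_r - ll_f)
  if (chi2 < -1e-6)
    stop("negative likelihood-ratio statistic: optimisation failure ",
         "(reduced model exceeds full model likelihood)")
  chi2 <- max(chi2, 0)
  p <- if (mixture && df == 1) {
    0.5 * stats::pchisq(chi2, 1, lower.tail = FALSE) + 0.5 * (chi2 <= 0)
  } else {
    stats::pchisq(chi2, df, lower.tail = FALSE)
  }
  list(chi2 = chi2, df = df, p = p)
}

#' Broad-sense heritability from a univariate fit
#'
#' `(sigma2_A + sigma2_D) / total variance`, with a delta-method standard
#' error from the estimated component covariance matrix.  Also available
#' directly as components of the printed [pedvar()] output.
#'
#' @param fit A univariate `pedvar_fit`, or a named numeric vector of
#'   variance components (then no SE is computed).
#' @return c(h2, se).
#' @examples
#' broad_h2(c(A = 0.11, D = 0.28, H = 0.066, E = 0.34))  # 0.494
#' @export
broad_h2 <- function(fit) {
  if (inherits(fit, "pedvar_fit")) {
    stopifnot(fit$ntrait == 1)
    return(c(h2 = fit$broad_h2, se = fit$broad_h2_se))
  }
  sigma2 <- fit
  tot <- sum(sigma2)
  if (tot <= 0) stop("zero total variance")
  c(h2 = sum(sigma2[names(sigma2) %in% c("A", "D")]) / tot, se = NA_real_)
}

#' Decompose the cross-trait phenotypic covariance
#'
#' The proportion of the phenotypic covariance between the two traits that
#' each variance component accounts for:
#' `share_c = C_c[1,2] / sum_c' C_c'[1,2]`.
#'
#' @param bfit A bivariate `pedvar_fit`.
#' @return Named proportions summing to 1.
#' @export
covariance_decomposition <- function(bfit) {
  stopifnot(inherits(bfit, "pedvar_fit"), bfit$ntrait == 2)
  cross <- vapply(bfit$C, function(Cc) Cc[1, 2], 0)
  tot <- sum(cross)
  if (abs(tot) < 1e-10)
    stop("total cross-trait covariance is numerically zero")
  cross / tot
}
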
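#' @export
print.pedvar_fit <- function(x, digits = 3, ...) {
  cat("Pedigree variance-component model (",
      paste(x$components, collapse = ""), "), ",
      if (x$ntrait == 2) "bivariate" else "univariate", "\n", sep = "")
  cat("  traits:", paste(x$traits, collapse = ", "),
      "  n =", x$n, " families =", x$nfam, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10), "\n")
  if (x$ntrait == 1) {
    est <- format(round(x$sigma2, digits))
    est[x$boundary] <- paste0(est[x$boundary], "*")
    cat("  variance components:\n")
    print(noquote(est))
    if (any(x$boundary)) cat("  (* at the zero boundary)\n")
  } else {
    cat("  cross-trait correlations:\n")
    print(round(x$r, digits))
  }
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' Summarise a pedigree variance-component fit
#'
#' For a univariate fit: component estimates with standard errors, the
#' proportion of total variance per component, broad-sense heritability
#' `(A + D) / total` with its delta-method standard error, and the fixed
#' effects.  For a bivariate fit: per-component 2x2 covariance matrices,
#' cross-trait correlations, the combined genetic correlation and the
#' decomposition of the phenotypic covariance.
#'
#' @param object A `pedvar_fit`.
#' @param ... Unused.
#' @export
summary.pedvar_fit <- function(object, ...) {
  out <- list(fit = object)
  if (object$ntrait == 1) {
    out$table <- data.frame(
      component = object$components,
      estimate = unname(object$sigma2),
      se = unname(object$se),
      proportion = unname(object$sigma2 / object$total_variance))
    out$broad_h2 <- c(estimate = object$broad_h2, se = object$broad_h2_se)
  } else {
    out$r <- object$r
    out$r_genetic_combined <- object$r_genetic_combined
    out$cov_share <- object$cov_share
    out$phen_cov <- object$phen_cov
  }
  bse <- sqrt(diag(object$beta_vcov))
  out$fixed <- data.frame(estimate = object$beta, se = bse,
                          z = object$beta / bse)
  class(out) <- "summary.pedvar_fit"
  out
}

#' @export
print.summary.pedvar_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (x$fit$ntrait == 1) {
    cat("\nVariance components:\n")
    print(x$table, digits = digits, row.names = FALSE)
    cat(sprintf("\nBroad-sense heritability: %.3f (SE %.3f)\n",
                x$broad_h2["estimate"], x$broad_h2["se"]))
  } else {
    cat("\nPer-component cross-trait correlations:\n")
    print(round(x$r, digits))
    cat(sprintf("Combined genetic correlation: %.3f\n",
                x$r_genetic_combined))
    cat(sprintf("Phenotypic covariance: %.3f\n", x$phen_cov))
    cat("Covariance shares:\n")
    print(round(x$cov_share, digits))
  }
  cat("\nFixed effects:\n")
  print(x$fixed, digits = digits)
  invisible(x)
}

#' @export
coef.pedvar_fit <- function(object, ...) object$beta

#' @export
logLik.pedvar_fit <- function(object, ...) {
  structure(object$loglik, df = object$np + length(object$beta),
            nobs = object$n, class = "logLik")
}

#' @export
vcov.pedvar_fit <- function(object, ...) object$beta_vcov

#' Extract variance-component estimates
#'
#' @param object A `pedvar_fit`.
#' @return Named numeric vector of variance components (univariate) or the
#'   list of per-component trait covariance matrices (bivariate).
#' @export
varcomp <- function(object) {
  stopifnot(inherits(object, "pedvar_fit"))
  if (object$ntrait == 1) object$sigma2 else object$C
}

#' @export
predict.pedvar_fit <- function(object, newdata, ...) {
  if (missing(newdata)) stop("supply newdata with the model covariates")
  f <- stats::formula(object$call$formula)
  rhs <- stats::delete.response(stats::terms(f))
  X <- stats::model.matrix(rhs, stats::model.frame(rhs, newdata,
                                                  na.action = stats::na.pass))
  if (object$ntrait == 1) return(drop(X %*% object$beta))
  p <- ncol(X)
  sapply(seq_len(object$ntrait), function(t)
    drop(X %*% object$beta[seq_len(p) + (t - 1) * p])) |>
    `colnames<-`(object$traits)
}

#' @export
residuals.pedvar_fit <- function(object, ...) {
  ## marginal residuals y - X beta over the fitted observation blocks
  unlist(lapply(object$blocks$fams, function(f)
    f$y - drop(f$X %*% object$beta)))
}

#' @export
fitted.pedvar_fit <- function(object, ...) {
  unlist(lapply(object$blocks$fams, function(f) drop(f$X %*% object$beta)))
}

#' Simulate responses from a fitted model
#'
#' Draws new observation vectors from the fitted multivariate-normal family
#' blocks (fixed effects plus correlated A/D/H/E deviations).
#'
#' @param object A `pedvar_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of length `nsim`; each element is a numeric vector in the
#'   fitted observation order.
#' @export
simulate.pedvar_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Clist <- if (object$ntrait == 1)
    .theta_to_C(object$theta, object$components, 1)
  else .theta_to_C(object$theta, object$components, 2)
  draws <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    draws[[s]] <- unlist(lapply(object$blocks$fams, function(f) {
      n <- length(f$y)
      V <- matrix(0, n, n)
      for (k in seq_along(Clist))
        V <- V + Clist[[k]][f$trait, f$trait, drop = FALSE] *
          f$K[[k]][f$ind, f$ind, drop = FALSE]
      mu <- drop(f$X %*% object$beta)
      L <- t(chol(V + diag(1e-10, n)))
      mu + drop(L %*% stats::rnorm(n))
    }))
  }
  draws
}

#' @export
plot.pedvar_fit <- function(x, ...) {
  if (x$ntrait == 1) {
    prop <- x$sigma2 / x$total_variance
    graphics::barplot(prop, names.arg = x$components,
                      ylab = "proportion of phenotypic variance",
                      main = paste(x$traits, collapse = ", "), ...)
  } else {
    graphics::barplot(x$cov_share, names.arg = x$components,
                      ylab = "share of phenotypic covariance",
                      main = paste(x$traits, collapse = " / "), ...)
  }
  invisible(x)
}

#' @export
anova.pedvar_fit <- function(object, ..., mixture = FALSE) {
  others <- list(...)
  others <- others[vapply(others, inherits, TRUE, "pedvar_fit")]
  if (!length(others))
    stop("supply a second (nested) pedvar_fit to compare")
  red <- others[[1]]
  lr_test(object, red, mixture = mixture)
}
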
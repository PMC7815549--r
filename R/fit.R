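#' Fit an A/D/H/E variance-component model on extended pedigrees
#'
#' Maximum-likelihood estimation of additive-genetic (A), dominance (D),
#' shared-household (H) and unique-environment (E) variance components on
#' extended twin-family pedigrees, with fixed effects (typically age and
#' sex) on the mean.  Each family is an independent multivariate-normal
#' block with covariance
#' `sigma2_A * 2*Phi + sigma2_D * Delta7 + sigma2_H * Hsh + sigma2_E * I`.
#' A two-column response (`cbind(trait1, trait2) ~ ...`) fits the bivariate
#' model in which every component has a 2x2 trait covariance matrix
#' parameterised by its Cholesky factor (kept positive semi-definite by
#' construction), the family covariance being the Kronecker combination of
#' trait and relationship structure.
#'
#' Fixed effects are profiled out (generalised least squares at each
#' covariance evaluation); variance parameters are maximised by bounded
#' quasi-Newton iterations from several dispersed starts and the best
#' likelihood is kept.  Standard errors come from the inverse observed
#' information (central finite differences) on the interior of the
#' parameter space; components estimated at the zero boundary are flagged
#' and reported without a standard error.
#'
#' @param formula Model formula, e.g. `na ~ age + sex` or
#'   `cbind(na, si) ~ age + sex`.  The same mean model is used for both
#'   traits of a bivariate fit (with separate coefficients).
#' @param data data.frame holding the response(s), covariates and an
#'   individual-id column.
#' @param pedigree A [pedigree()] covering the phenotyped individuals.
#' @param components Character: subset of `"A"`, `"D"`, `"H"`, `"E"` (or a
#'   single string like `"ADHE"`).  `E` is always included; `D` requires
#'   `A`.
#' @param ages Named vector of ages used for the household rule; defaults
#'   to the `age` column of `data` (missing ages are treated as adult).
#' @param transform `"none"` or `"int"` (rank-based inverse normal
#'   transform of each response before fitting, see [inverse_normal()]).
#' @param id Name of the individual-id column in `data`.
#' @param n_starts Number of dispersed optimisation starts (at least 3).
#' @param se Compute standard errors (set `FALSE` inside simulation loops
#'   that do not need them).
#' @param rmats Optional precomputed [relationship_matrices()] for the
#'   pedigree (avoids recomputation in simulation loops).
#' @param control Passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return An object of class `pedvar_fit`; see [summary.pedvar_fit()].
#'   Key elements: `sigma2` (named variance estimates; for a bivariate fit
#'   `C`, the per-component 2x2 matrices), `se`, `beta`, `loglik`, `np`
#'   (number of variance parameters), `n`, `nfam`, `converged`, `boundary`,
#'   and for bivariate fits `r` (per-component cross-trait correlations),
#'   `r_genetic_combined` and `cov_share`.
#' @seealso [broad_h2()], [lr_test()], [covariance_decomposition()]
#' @export
pedvar <- function(formula, data, pedigree, components = c("A", "D", "H", "E"),
                   ages = NULL, transform = c("none", "int"),
                   id = "individual_id", n_starts = 3, se = TRUE,
                   rmats = NULL, control = list()) {
  cl <- match.call()
  transform <- match.arg(transform)
  comps <- .check_components(components)
  stopifnot(inherits(pedigree, "pedigree"))
  if (!id %in% names(data)) stop("data lacks id column '", id, "'")
  if (!any(data[[id]] %in% pedigree$df$individual_id))
    stop("no overlap between phenotype individual ids and the pedigree")

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  Y <- stats::model.response(mf)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(NULL, deparse(formula[[2]])))
  ntrait <- ncol(Y)
  if (ntrait > 2) stop("at most two traits are supported")
  traits <- colnames(Y)
  if (transform == "int") for (t in seq_len(ntrait)) Y[, t] <- inverse_normal(Y[, t])
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ids <- as.character(data[[id]])

  if (is.null(ages) && "age" %in% names(data))
    ages <- stats::setNames(as.numeric(data$age), ids)
  if (is.null(rmats)) rmats <- relationship_matrices(pedigree, ages)

  blocks <- .family_blocks(rmats, ids, Y, X, comps)
  if (!length(blocks$fams)) stop("no phenotyped family blocks to fit")
  p <- ncol(X) * ntrait

  ## objective and analytic gradient share per-theta GLS solves via a cache
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  eval_terms <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$val)
    Clist <- .theta_to_C(theta, comps, ntrait)
    t <- .ll_terms_cpp(blocks$fams, Clist)
    val <- list(ok = t$ok, Clist = Clist)
    if (t$ok) {
      beta <- tryCatch(solve(t$XtX, t$Xty), error = function(e) NULL)
      if (is.null(beta)) val$ok <- FALSE
      else {
        val$beta <- beta
        val$nll <- 0.5 * (t$n * log(2 * pi) + t$logdet + t$yty -
                            sum(beta * t$Xty))
      }
    }
    cache$theta <- theta
    cache$val <- val
    val
  }
  nll <- function(theta) {
    v <- eval_terms(theta)
    if (!v$ok) return(1e10)
    v$nll
  }
  gr <- function(theta) {
    v <- eval_terms(theta)
    if (!v$ok) return(rep(0, length(theta)))
    g <- .ll_grad_cpp(blocks$fams, v$Clist, v$beta)
    .chain_grad(g, theta, comps, ntrait)
  }

  svar <- apply(Y, 2, stats::var, na.rm = TRUE)
  starts <- .make_starts(comps, ntrait, svar, max(3L, n_starts))
  bounds <- .theta_bounds(comps, ntrait)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, nll, gr, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = utils::modifyList(list(maxit = 500), control)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all optimisation starts failed")
  converged <- best$convergence == 0
  theta <- best$par

  ## final pass for fixed effects
  Clist <- .theta_to_C(theta, comps, ntrait)
  tt <- .ll_terms_cpp(blocks$fams, Clist)
  beta <- drop(solve(tt$XtX, tt$Xty))
  beta_vcov <- solve(tt$XtX)
  bn <- colnames(X)
  if (ntrait == 2) bn <- as.vector(outer(bn, traits,
                                         function(b, t) paste(t, b, sep = ":")))
  names(beta) <- bn
  dimnames(beta_vcov) <- list(bn, bn)
  loglik <- -best$value

  fit <- list(call = cl, components = comps, traits = traits,
              ntrait = ntrait, theta = theta, beta = beta,
              beta_vcov = beta_vcov, loglik = loglik,
              np = length(theta), n = tt$n, nfam = blocks$nfam,
              nblock = length(blocks$fams), converged = converged,
              transform = transform, blocks = blocks)

  if (ntrait == 1) {
    sigma2 <- stats::setNames(theta, comps)
    boundary <- sigma2 < 1e-6
    fit$sigma2 <- sigma2
    fit$boundary <- boundary
    fit$total_variance <- sum(sigma2)
    vc <- matrix(0, length(comps), length(comps),
                 dimnames = list(comps, comps))
    sev <- rep(NA_real_, length(comps))
    if (se) {
      int <- which(!boundary)
      if (length(int)) {
        ## observed information = jacobian of the analytic gradient on the
        ## interior components (central differences)
        H <- tryCatch(numDeriv::jacobian(function(th) {
          full <- theta; full[int] <- th; gr(full)[int]
        }, theta[int], method.args = list(r = 2)), error = function(e) NULL)
        if (!is.null(H)) H <- (H + t(H)) / 2
        Vi <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(Vi)) {
          vc[int, int] <- Vi
          sev[int] <- sqrt(pmax(diag(Vi), 0))
        }
      }
    }
    fit$vcov_sigma2 <- vc
    fit$se <- stats::setNames(sev, comps)
    h2 <- .broad_h2_from(sigma2, vc)
    fit$broad_h2 <- h2$h2
    fit$broad_h2_se <- h2$se
  } else {
    fit$C <- .theta_to_C(theta, comps, 2)
    names(fit$C) <- comps
    fit$r <- vapply(fit$C, function(Cc)
      if (Cc[1, 1] > 1e-10 && Cc[2, 2] > 1e-10)
        Cc[1, 2] / sqrt(Cc[1, 1] * Cc[2, 2]) else NA_real_, 0)
    G <- Reduce(`+`, fit$C[intersect(c("A", "D"), comps)])
    fit$r_genetic_combined <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
    cross <- vapply(fit$C, function(Cc) Cc[1, 2], 0)
    fit$cov_share <- cross / sum(cross)
    fit$phen_cov <- sum(cross)
    fit$boundary <- vapply(fit$C, function(Cc)
      min(Cc[1, 1], Cc[2, 2]) < 1e-6, TRUE)
    if (se) {
      H <- tryCatch(numDeriv::jacobian(gr, theta, method.args = list(r = 2)),
                    error = function(e) NULL)
      if (!is.null(H)) H <- (H + t(H)) / 2
      Vth <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vth)) {
        fit$vcov_theta <- Vth
        der <- function(th) .bi_derived(th, comps)
        J <- tryCatch(numDeriv::jacobian(der, theta), error = function(e) NULL)
        if (!is.null(J)) {
          Vd <- J %*% Vth %*% t(J)
          d <- der(theta)
          fit$derived_se <- stats::setNames(sqrt(pmax(diag(Vd), 0)), names(d))
        }
      }
    }
  }
  class(fit) <- "pedvar_fit"
  fit
}

.check_components <- function(components) {
  if (length(components) == 1L && nchar(components) > 1L)
    components <- strsplit(components, "")[[1]]
  comps <- intersect(c("A", "D", "H", "E"), toupper(components))
  if (!setequal(comps, toupper(components)))
    stop("components must be a subset of A, D, H, E")
  if (!"E" %in% comps) comps <- c(comps, "E")
  if ("D" %in% comps && !"A" %in% comps)
    stop("a dominance component requires the additive component")
  comps
}

## build per-family observation blocks, splitting each family into
## independent sub-blocks wherever the combined relationship structure is
## zero (identical likelihood, smaller factorisations)
.family_blocks <- function(rmats, ids, Y, X, comps) {
  ntrait <- ncol(Y)
  fams <- list()
  nfam <- 0L
  for (fam in names(rmats)) {
    rm <- rmats[[fam]]
    keep <- rm$ids[rm$ids %in% ids]
    if (!length(keep)) next
    rows <- match(keep, ids)
    obsY <- Y[rows, , drop = FALSE]
    okX <- stats::complete.cases(X[rows, , drop = FALSE])
    hasobs <- rowSums(!is.na(obsY)) > 0 & okX
    if (!any(hasobs)) next
    keep <- keep[hasobs]; rows <- rows[hasobs]
    nfam <- nfam + 1L
    A <- rm$additive[keep, keep, drop = FALSE]
    D <- rm$dominance[keep, keep, drop = FALSE]
    H <- rm$household[keep, keep, drop = FALSE]
    conn <- (abs(A) > 1e-12) | (abs(D) > 1e-12) | (H > 0)
    comp_id <- .connected_components(conn)
    for (g in unique(comp_id)) {
      sel <- which(comp_id == g)
      Ksub <- lapply(comps, function(cc) switch(cc,
        A = A[sel, sel, drop = FALSE],
        D = D[sel, sel, drop = FALSE],
        H = H[sel, sel, drop = FALSE],
        E = diag(length(sel))))
      ind <- integer(0); trait <- integer(0); yv <- numeric(0)
      Xl <- list()
      for (t in seq_len(ntrait)) {
        for (k in seq_along(sel)) {
          r <- rows[sel[k]]
          if (is.na(Y[r, t])) next
          ind <- c(ind, k); trait <- c(trait, t)
          yv <- c(yv, Y[r, t])
          xr <- X[r, , drop = FALSE]
          if (ntrait == 2) {
            z <- matrix(0, 1, 2 * ncol(X))
            z[1, seq_len(ncol(X)) + (t - 1) * ncol(X)] <- xr
            xr <- z
          }
          Xl[[length(Xl) + 1L]] <- xr
        }
      }
      if (!length(yv)) next
      fams[[length(fams) + 1L]] <-
        list(K = Ksub, ind = as.integer(ind), trait = as.integer(trait),
             X = do.call(rbind, Xl), y = yv)
    }
  }
  list(fams = fams, nfam = nfam)
}

.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

## parameter vector <-> per-component trait covariance matrices
.theta_to_C <- function(theta, comps, ntrait) {
  if (ntrait == 1) return(lapply(theta, function(s) matrix(s, 1, 1)))
  out <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    l <- theta[(k - 1) * 3 + 1:3]
    L <- matrix(c(l[1], l[2], 0, l[3]), 2, 2)
    out[[k]] <- L %*% t(L)
  }
  out
}

## chain rule from gradients w.r.t. symmetric C entries (lower triangle,
## column-major per component) to the optimisation parameters
.chain_grad <- function(g, theta, comps, ntrait) {
  if (ntrait == 1) return(as.numeric(g))
  out <- numeric(length(theta))
  for (k in seq_along(comps)) {
    gi <- g[(k - 1) * 3 + 1:3]          # dC11, dC21, dC22
    l <- theta[(k - 1) * 3 + 1:3]       # l11, l21, l22
    out[(k - 1) * 3 + 1] <- 2 * l[1] * gi[1] + l[2] * gi[2]
    out[(k - 1) * 3 + 2] <- l[1] * gi[2] + 2 * l[2] * gi[3]
    out[(k - 1) * 3 + 3] <- 2 * l[3] * gi[3]
  }
  out
}

.theta_bounds <- function(comps, ntrait) {
  if (ntrait == 1) {
    lower <- ifelse(comps == "E", 1e-6, 0)
    upper <- rep(Inf, length(comps))
  } else {
    lower <- rep(c(0, -Inf, 0), length(comps))
    lower[rep(comps == "E", each = 3) & rep(c(TRUE, FALSE, TRUE),
                                            length(comps))] <- 1e-4
    upper <- rep(Inf, 3 * length(comps))
  }
  list(lower = lower, upper = upper)
}

.make_starts <- function(comps, ntrait, svar, n_starts) {
  k <- length(comps)
  mixes <- list(rep(1 / k, k),
                ifelse(comps == "E", 0.7, 0.3 / max(1, k - 1)),
                ifelse(comps %in% c("A", "E"), 0.4, 0.2 / max(1, k - 2)))
  while (length(mixes) < n_starts) {
    w <- stats::runif(k, 0.05, 1)
    mixes[[length(mixes) + 1L]] <- w / sum(w)
  }
  mixes <- mixes[seq_len(n_starts)]
  lapply(mixes, function(w) {
    if (ntrait == 1) return(pmax(w * mean(svar), 1e-4))
    th <- numeric(0)
    for (kk in seq_len(k)) {
      s1 <- sqrt(w[kk] * svar[1]); s2 <- sqrt(w[kk] * svar[2])
      th <- c(th, s1, 0.3 * s2, sqrt(max(s2^2 - (0.3 * s2)^2, 1e-6)))
    }
    th
  })
}

.broad_h2_from <- function(sigma2, vc) {
  tot <- sum(sigma2)
  if (tot <= 0) return(list(h2 = NA_real_, se = NA_real_))
  g <- sum(sigma2[names(sigma2) %in% c("A", "D")])
  h2 <- g / tot
  grad <- ifelse(names(sigma2) %in% c("A", "D"),
                 (tot - g) / tot^2, -g / tot^2)
  se <- sqrt(max(drop(t(grad) %*% vc %*% grad), 0))
  list(h2 = h2, se = se)
}

## derived bivariate quantities as a smooth function of theta (for the
## delta method): per-component correlations, combined genetic correlation,
## covariance shares
.bi_derived <- function(theta, comps) {
  C <- .theta_to_C(theta, comps, 2)
  names(C) <- comps
  r <- vapply(C, function(Cc) Cc[1, 2] / sqrt(Cc[1, 1] * Cc[2, 2]), 0)
  G <- Reduce(`+`, C[intersect(c("A", "D"), comps)])
  rg <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
  cross <- vapply(C, function(Cc) Cc[1, 2], 0)
  share <- cross / sum(cross)
  c(stats::setNames(r, paste0("r_", comps)), r_genetic = rg,
    stats::setNames(share, paste0("share_", comps)))
}

#' Per-family model covariance matrix
#'
#' The covariance implied by variance components for one family:
#' `sigma2_A * additive + sigma2_D * dominance + sigma2_H * household +
#' sigma2_E * I`.  Mostly useful for inspection and testing; [pedvar()]
#' assembles these internally.
#'
#' @param rm A `relmat` (one element of [relationship_matrices()]).
#' @param sigma2 Named vector with entries among `A`, `D`, `H`, `E`.
#' @return Symmetric covariance matrix over the family ids.
#' @export
family_covariance <- function(rm, sigma2) {
  stopifnot(inherits(rm, "relmat"))
  n <- length(rm$ids)
  V <- matrix(0, n, n, dimnames = list(rm$ids, rm$ids))
  for (cc in names(sigma2)) {
    M <- switch(cc, A = rm$additive, D = rm$dominance, H = rm$household,
                E = diag(n), stop("unknown component ", cc))
    V <- V + sigma2[[cc]] * M
  }
  ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    warning("covariance numerically non-PSD; adding 1e-10 jitter")
    V <- V + diag(1e-10, n)
  }
  V
}

#' Log-likelihood of data under given parameter values
#'
#' Evaluates (without optimising) the multivariate-normal log-likelihood of
#' phenotypes on a pedigree for fixed variance components and fixed-effect
#' coefficients.  Families contribute independent blocks; missing
#' phenotypes are dropped element-wise.
#'
#' @inheritParams pedvar
#' @param sigma2 Named variance components (univariate).
#' @param beta Fixed-effect coefficients in the order of
#'   `model.matrix(formula, data)`.
#' @return The log-likelihood (scalar).
#' @export
pedvar_loglik <- function(formula, data, pedigree, sigma2, beta,
                          ages = NULL, id = "individual_id") {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  Y <- stats::model.response(mf)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  stopifnot(ncol(Y) == 1)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ids <- as.character(data[[id]])
  if (is.null(ages) && "age" %in% names(data))
    ages <- stats::setNames(as.numeric(data$age), ids)
  rmats <- relationship_matrices(pedigree, ages)
  comps <- names(sigma2)
  blocks <- .family_blocks(rmats, ids, Y, X, comps)
  t <- .ll_terms_cpp(blocks$fams, .theta_to_C(as.numeric(sigma2), comps, 1))
  if (!t$ok) stop("singular family covariance")
  ## reassemble the non-profiled quadratic form:
  ## (y - Xb)' V^-1 (y - Xb) = yty - 2 b'Xty + b'XtX b
  q <- t$yty - 2 * sum(beta * t$Xty) + drop(t(beta) %*% t$XtX %*% beta)
  -0.5 * (t$n * log(2 * pi) + t$logdet + q)
}
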
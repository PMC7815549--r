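# Independent oracles: gene-dropping Monte Carlo for relatedness, a direct
# dense multivariate-normal density, and a brute-force tetrachoric
# likelihood grid.  These deliberately share no code with the package
# internals.

# Drop founder alleles down one family; returns per-drop allele matrices.
gene_drop <- function(ped, family, ndrop = 2e5, seed = 1) {
  df <- ped$df[ped$df$family_id == family, , drop = FALSE]
  ids <- df$individual_id
  n <- nrow(df)
  fa <- match(df$father_id, ids)
  mo <- match(df$mother_id, ids)
  mz <- df$mz_group
  set.seed(seed)
  pat <- mat <- matrix(0L, ndrop, n)
  cnt <- 0L
  for (i in seq_len(n)) {
    if (!is.na(mz[i])) {
      rep_i <- which(!is.na(mz) & mz == mz[i])[1]
      if (rep_i < i) {              # co-twin: copy the representative
        pat[, i] <- pat[, rep_i]
        mat[, i] <- mat[, rep_i]
        next
      }
    }
    if (is.na(fa[i])) {
      pat[, i] <- cnt + 1L
      mat[, i] <- cnt + 2L
      cnt <- cnt + 2L
    } else {
      s1 <- stats::runif(ndrop) < 0.5
      pat[, i] <- ifelse(s1, pat[, fa[i]], mat[, fa[i]])
      s2 <- stats::runif(ndrop) < 0.5
      mat[, i] <- ifelse(s2, pat[, mo[i]], mat[, mo[i]])
    }
  }
  list(pat = pat, mat = mat, ids = ids, ndrop = ndrop)
}

# Monte-Carlo additive (2*phi) and dominance (Delta7) estimates for a pair,
# with Monte-Carlo standard errors.
ibd_pair <- function(gd, i, j) {
  a <- match(i, gd$ids); b <- match(j, gd$ids)
  s <- (gd$pat[, a] == gd$pat[, b]) + (gd$pat[, a] == gd$mat[, b]) +
       (gd$mat[, a] == gd$pat[, b]) + (gd$mat[, a] == gd$mat[, b])
  both <- s == 2
  list(additive = mean(s) / 2, dominance = mean(both),
       se_additive = stats::sd(s / 2) / sqrt(gd$ndrop),
       se_dominance = stats::sd(both) / sqrt(gd$ndrop))
}

# Direct dense Gaussian log density (no per-family decomposition).
mvn_loglik_direct <- function(y, mu, V) {
  r <- y - mu
  n <- length(y)
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% solve(V, r)))
}

# Tetrachoric correlation by brute-force likelihood maximisation over a
# rho grid with thresholds fixed at the marginal normal quantiles.
tetra_grid <- function(tab, step = 1e-4) {
  n <- sum(tab)
  h <- qnorm(sum(tab[2, ]) / n)
  k <- qnorm(sum(tab[, 2]) / n)
  rhos <- seq(-0.999, 0.999, by = step)
  ll <- vapply(rhos, function(r) {
    S <- matrix(c(1, r, r, 1), 2)
    p22 <- mvtnorm::pmvnorm(lower = c(h, k), upper = c(Inf, Inf),
                            sigma = S)[1]
    p2r <- 1 - pnorm(h); p2c <- 1 - pnorm(k)
    p <- pmax(c(1 - p2r - p2c + p22, p2c - p22, p2r - p22, p22), 1e-12)
    sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(p))
  }, 0)
  rhos[which.max(ll)]
}

# Textbook product-moment correlation evaluated without stats::cor.
pearson_direct <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
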
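test_that("family covariance combines component matrices correctly", {
  ped <- mz_family()
  rm <- relationship_matrices(ped, ages = c(t1 = 16, t2 = 16))[[1]]
  sig <- c(A = 0.11, D = 0.28, H = 0.066, E = 0.34)
  V <- family_covariance(rm, sig)
  ## MZ pair sharing a household: off-diagonal A + D + H, diagonal the total
  expect_equal(V["t1", "t2"], 0.11 + 0.28 + 0.066)
  expect_equal(V["t1", "t1"], 0.796)
  ## spouse pair sharing a household: covariance is the household variance
  expect_equal(V["pa", "ma"], 0.066)
  ## singleton with only E
  single <- pedigree(ped_df(list("x", NA, NA, "male")))
  V1 <- family_covariance(relationship_matrices(single)[[1]], c(E = 1))
  expect_equal(unname(V1), matrix(1))
})

test_that("log-likelihood matches a direct dense evaluation", {
  ## single standard-normal observation
  single <- pedigree(ped_df(list("x", NA, NA, "male")))
  d1 <- data.frame(individual_id = "x", y = 0)
  ll1 <- pedvar_loglik(y ~ 1, d1, single, sigma2 = c(E = 1), beta = 0)
  expect_equal(ll1, -0.5 * log(2 * pi), tolerance = 1e-12)

  ## multi-family data against one dense joint evaluation
  cfg <- sim_config(n_families = 12, seed = 5)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  sig <- c(A = 0.12, D = 0.25, H = 0.07, E = 0.35)
  beta <- c(0.1, -0.004, 0.15)
  ll <- pedvar_loglik(na ~ age + sex, ph, sim$ped, sigma2 = sig,
                      beta = beta, ages = sim$ages)
  rmats <- relationship_matrices(sim$ped, sim$ages)
  blocks <- list()
  for (fam in names(rmats)) {
    rm <- rmats[[fam]]
    keep <- intersect(rm$ids, ph$individual_id)
    if (!length(keep)) next
    idx <- match(keep, rm$ids)
    V <- 0.12 * rm$additive[idx, idx] + 0.25 * rm$dominance[idx, idx] +
      0.07 * rm$household[idx, idx] + 0.35 * diag(length(idx))
    blocks[[fam]] <- list(ids = keep, V = V)
  }
  n <- sum(lengths(lapply(blocks, `[[`, "ids")))
  Vbig <- matrix(0, n, n)
  ids <- unlist(lapply(blocks, `[[`, "ids"))
  at <- 0
  for (b in blocks) {
    k <- length(b$ids)
    Vbig[at + seq_len(k), at + seq_len(k)] <- b$V
    at <- at + k
  }
  m <- match(ids, ph$individual_id)
  X <- cbind(1, ph$age[m], ph$sex[m] == "male")
  mu <- drop(X %*% beta)
  ll_direct <- mvn_loglik_direct(ph$na[m], mu, Vbig)
  expect_equal(ll, ll_direct, tolerance = 1e-8)
})

test_that("log-likelihood is additive over duplicated families", {
  ped <- mz_family()
  d <- data.frame(individual_id = c("t1", "t2"), y = c(0.3, -0.2))
  ll1 <- pedvar_loglik(y ~ 1, d, ped, sigma2 = c(A = 0.4, E = 0.6), beta = 0)
  df2 <- ped$df
  df2$family_id <- "f2"
  for (col in c("individual_id", "father_id", "mother_id", "mz_group"))
    df2[[col]] <- ifelse(is.na(df2[[col]]), NA, paste0("b.", df2[[col]]))
  ped2 <- pedigree(rbind(ped$df, df2))
  d2 <- rbind(d, data.frame(individual_id = c("b.t1", "b.t2"),
                            y = c(0.3, -0.2)))
  ll2 <- pedvar_loglik(y ~ 1, d2, ped2, sigma2 = c(A = 0.4, E = 0.6),
                       beta = 0)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("likelihood is invariant to family order", {
  cfg <- sim_config(n_families = 30, seed = 8)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  sig <- c(A = 0.1, D = 0.3, H = 0.06, E = 0.35)
  ll <- pedvar_loglik(na ~ age, ph, sim$ped, sig, beta = c(0, 0),
                      ages = sim$ages)
  set.seed(2)
  perm <- ph[sample.int(nrow(ph)), ]
  llp <- pedvar_loglik(na ~ age, perm, sim$ped, sig, beta = c(0, 0),
                       ages = sim$ages)
  expect_equal(ll, llp, tolerance = 1e-10)
})

test_that("component constraints are enforced", {
  expect_error(pedvar:::.check_components(c("D", "E")), "additive")
  expect_equal(pedvar:::.check_components("AD"), c("A", "D", "E"))
  expect_equal(pedvar:::.check_components("ADHE"), c("A", "D", "H", "E"))
  expect_error(pedvar:::.check_components("AXE"), "subset")
})

test_that("a household-free architecture drives the H estimate to zero", {
  cfg <- sim_config(n_families = 400, seed = 13,
                    sigma2 = cbind(na = c(A = 0.3, D = 0, H = 0, E = 0.7)),
                    r_comp = c(A = 0, D = 0, H = 0, E = 0))
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  fit <- pedvar(na ~ age + sex, ph, sim$ped, components = "AHE",
                rmats = attr(ph, "rmats"))
  expect_lt(fit$sigma2[["H"]], 0.05)
})

test_that("nested models never beat the full model likelihood", {
  cfg <- sim_config(n_families = 300, seed = 17)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  rmats <- attr(ph, "rmats")
  full <- pedvar(na ~ age + sex, ph, sim$ped, components = "ADHE",
                 rmats = rmats, se = FALSE)
  for (comps in c("ADE", "AHE", "AE")) {
    red <- pedvar(na ~ age + sex, ph, sim$ped, components = comps,
                  rmats = rmats, se = FALSE)
    expect_lte(red$loglik, full$loglik + 1e-4)
    lrt <- lr_test(full, red)
    expect_gte(lrt$chi2, -1e-6)
    expect_equal(lrt$df, full$np - red$np)
  }
})

test_that("pure twin data reproduces the Falconer-style moment solution", {
  ## with only MZ/DZ pairs (no parents, no household), ML ADE estimates
  ## solve the same moment equations: A = 4 rDZ - rMZ, D = 2 rMZ - 4 rDZ
  ## (scaled by the phenotypic variance)
  cfg <- sim_config(n_families = 4000, seed = 23,
                    p_obs_parent = 0, p_obs_sib = 0, p_obs_spouse = 0,
                    p_obs_offspring = 0, p_sib = 0, p_spouse = 0,
                    p_obs_twin_pair = c(both = 1, one = 0, none = 0),
                    age_twin_mean = 40, age_twin_sd = 5,
                    age_twin_range = c(25, 60),  # all adult: H inert
                    sigma2 = cbind(na = c(A = 0.2, D = 0.25, H = 0,
                                          E = 0.55)),
                    beta_age = 0, beta_sex = 0)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  fit <- pedvar(na ~ 1, ph, sim$ped, components = "ADE",
                rmats = attr(ph, "rmats"), se = FALSE)
  r_mz <- pearson_correlation(extract_pairs(sim$ped, ph, "MZ", "na"))
  r_dz <- pearson_correlation(extract_pairs(sim$ped, ph, "DZ", "na"))
  v <- var(ph$na)
  a_moment <- (4 * r_dz - r_mz) * v
  d_moment <- (2 * r_mz - 4 * r_dz) * v
  expect_lt(abs(fit$sigma2[["A"]] - a_moment), 0.08)
  expect_lt(abs(fit$sigma2[["D"]] - d_moment), 0.08)
  expect_lt(abs(fit$total_variance - v), 0.03)
})

test_that("LRT arithmetic and p-values behave", {
  out <- lr_test(-11422.35, -11444.53, df = 1)
  expect_equal(out$chi2, 44.36, tolerance = 1e-10)
  expect_lt(out$p, 0.001)
  same <- lr_test(-100, -100, df = 1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  mix <- lr_test(-100, -100.5, df = 1, mixture = TRUE)
  expect_equal(mix$p, 0.5 * pchisq(1, 1, lower.tail = FALSE))
  expect_error(lr_test(-101, -100, df = 1), "negative")
  expect_error(lr_test(-100, -101), "df required")
})

test_that("broad-sense heritability and its delta-method SE", {
  expect_equal(unname(broad_h2(c(A = 0.11, D = 0.28, H = 0.066,
                                 E = 0.34))["h2"]),
               0.39 / 0.796, tolerance = 1e-12)
  expect_equal(unname(broad_h2(c(A = 0, D = 0, E = 1))["h2"]), 0)
  ## against the fit-embedded value
  cfg <- sim_config(n_families = 300, seed = 29)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  fit <- pedvar(na ~ age + sex, ph, sim$ped, rmats = attr(ph, "rmats"))
  h <- broad_h2(fit)
  expect_equal(unname(h["h2"]),
               sum(fit$sigma2[c("A", "D")]) / sum(fit$sigma2))
  expect_true(is.finite(h["se"]) && h["se"] > 0)
})

test_that("bivariate fit on a duplicated trait hits the +1 boundary", {
  cfg <- sim_config(n_families = 150, seed = 37)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  ph$si <- ph$na
  fit <- pedvar(cbind(na, si) ~ age + sex, ph, sim$ped,
                rmats = attr(ph, "rmats"), se = FALSE)
  big <- fit$components[vapply(fit$C, function(Cc) min(diag(Cc)), 0) > 0.02]
  expect_true(all(fit$r[big] > 0.97))
  expect_equal(sum(fit$cov_share), 1, tolerance = 1e-8)
})

test_that("bivariate fit recovers cross-trait correlations", {
  cfg <- sim_config(n_families = 800, seed = 41)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  fit <- pedvar(cbind(na, si) ~ age + sex, ph, sim$ped,
                rmats = attr(ph, "rmats"))
  expect_true(fit$converged)
  ## combined genetic correlation: truth approximately 0.66
  expect_lt(abs(fit$r_genetic_combined - 0.66), 0.15)
  expect_equal(sum(fit$cov_share), 1, tolerance = 1e-8)
  expect_equal(unname(covariance_decomposition(fit)), unname(fit$cov_share))
  ## independent traits: correlations near zero
  cfg0 <- sim_config(n_families = 500, seed = 43,
                     r_comp = c(A = 0, D = 0, H = 0, E = 0))
  sim0 <- simulate_pedigrees(cfg0)
  ph0 <- simulate_phenotypes(sim0, cfg0)
  ph0 <- ph0[ph0$phenotyped, ]
  fit0 <- pedvar(cbind(na, si) ~ age + sex, ph0, sim0$ped,
                 rmats = attr(ph0, "rmats"), se = FALSE)
  expect_lt(abs(fit0$phen_cov), 0.06)
})

test_that("model methods expose coherent summaries", {
  cfg <- sim_config(n_families = 150, seed = 47)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  ph <- ph[ph$phenotyped, ]
  fit <- pedvar(na ~ age + sex, ph, sim$ped, rmats = attr(ph, "rmats"))
  expect_output(print(fit), "variance components")
  s <- summary(fit)
  expect_output(print(s), "Broad-sense heritability")
  expect_equal(sum(s$table$proportion), 1, tolerance = 1e-10)
  expect_named(coef(fit), c("(Intercept)", "age", "sexmale"))
  expect_equal(attr(logLik(fit), "nobs"), fit$n)
  expect_equal(dim(vcov(fit)), c(3, 3))
  pr <- predict(fit, newdata = data.frame(age = c(20, 50),
                                          sex = c("male", "female")))
  expect_length(pr, 2)
  res <- residuals(fit)
  expect_length(res, fit$n)
  expect_equal(unname(fitted(fit) + res),
               unname(unlist(lapply(fit$blocks$fams, `[[`, "y"))))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_length(sims[[1]], fit$n)
  ## anova wraps the LRT
  red <- pedvar(na ~ age + sex, ph, sim$ped, components = "ADE",
                rmats = attr(ph, "rmats"), se = FALSE)
  a <- anova(fit, red)
  expect_equal(a$chi2, -2 * (red$loglik - fit$loglik), tolerance = 1e-8)
})
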
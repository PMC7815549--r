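test_that("pedigree simulation is deterministic under the seed", {
  cfg <- sim_config(n_families = 40, seed = 5)
  s1 <- simulate_pedigrees(cfg)
  s2 <- simulate_pedigrees(cfg)
  expect_identical(s1$ped$df, s2$ped$df)
  expect_identical(s1$info, s2$info)
  s3 <- simulate_pedigrees(sim_config(n_families = 40, seed = 6))
  expect_false(identical(s1$info$phenotyped, s3$info$phenotyped))
})

test_that("every simulated family has one twin pair with declared zygosity", {
  cfg <- sim_config(n_families = 60, seed = 9)
  sim <- simulate_pedigrees(cfg)
  df <- sim$ped$df
  for (fam in unique(df$family_id)) {
    d <- df[df$family_id == fam, ]
    tw <- d[grepl("\\.t[12]$", d$individual_id), ]
    expect_equal(nrow(tw), 2)
    expect_equal(tw$birth_year[1], tw$birth_year[2])
    mzg <- unique(na.omit(d$mz_group))
    expect_lte(length(mzg), 1)
  }
})

test_that("phenotyped composition tracks the registry-style sample", {
  cfg <- sim_config(n_families = 4000, seed = 15)
  sim <- simulate_pedigrees(cfg)
  obs <- sim$info[sim$info$phenotyped, ]
  mz_ids <- sim$ped$df$individual_id[!is.na(sim$ped$df$mz_group)]
  ## MZ individuals about 24% of the phenotyped sample (Dutch-registry mix)
  mz_share <- mean(obs$individual_id %in% mz_ids)
  expect_lt(abs(mz_share - 7380 / 30433), 0.02)
  ## about 2.7 phenotyped members per family
  expect_lt(abs(nrow(obs) / cfg$n_families - 30433 / 11106), 0.3)
  ## role mean ages near the configured targets
  expect_lt(abs(mean(obs$age[obs$role == "twin"]) - 28.3), 1.5)
  expect_lt(abs(mean(obs$age[obs$role == "parent"]) - 55.8), 1.5)
})

test_that("phenotype generation obeys the generative covariance algebra", {
  ## pure unique environment: MZ correlation near zero
  cfg0 <- sim_config(n_families = 2500, seed = 19,
                     sigma2 = cbind(na = c(A = 0, D = 0, H = 0, E = 1)),
                     p_obs_twin_pair = c(both = 1, one = 0, none = 0))
  sim0 <- simulate_pedigrees(cfg0)
  ph0 <- simulate_phenotypes(sim0, cfg0)
  tw <- ph0[ph0$role == "twin", ]
  mz_ids <- sim0$ped$df$individual_id[!is.na(sim0$ped$df$mz_group)]
  ps <- extract_pairs(sim0$ped, tw[tw$individual_id %in% mz_ids, ],
                      "MZ", "na")
  expect_lt(abs(pearson_correlation(ps)), 0.05)

  ## doubling all variances doubles the empirical variance
  cfg1 <- sim_config(n_families = 2500, seed = 20, beta_age = 0,
                     beta_sex = 0)
  sim1 <- simulate_pedigrees(cfg1)
  ph1 <- simulate_phenotypes(sim1, cfg1)
  cfg2 <- cfg1
  cfg2$sigma2 <- 2 * cfg1$sigma2
  ph2 <- simulate_phenotypes(sim1, cfg2)
  expect_lt(abs(var(ph2$na) / var(ph1$na) - 2), 0.1)
})

test_that("relative-pair covariances match sigma_A 2Phi + sigma_D Delta7 +
           sigma_H s", {
  cfg <- sim_config(n_families = 3500, seed = 25,
                    p_obs_twin_pair = c(both = 1, one = 0, none = 0),
                    p_obs_parent = 1, p_obs_sib = 1,
                    beta_age = 0, beta_sex = 0)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  sig <- cfg$sigma2[, "na"]
  ## adult (non-cohabiting) relative classes: expected correlation
  ## (sA * a + sD * d) / total
  adult <- ph[ph$age > 18, ]
  tot <- sum(sig)
  cases <- list(DZ = c(0.5, 0.25), sib = c(0.5, 0.25),
                `father-daughter` = c(0.5, 0))
  for (rel in names(cases)) {
    ps <- extract_pairs(sim$ped, adult, rel, "na")
    ## drop pairs where either member is a minor sharing a household
    th <- (sig["A"] * cases[[rel]][1] + sig["D"] * cases[[rel]][2]) / tot
    expect_lt(abs(pearson_correlation(ps) - th), 3.5 / sqrt(ps$n))
  }
})

test_that("item simulation respects the scoring rules", {
  cfg <- sim_config(n_families = 120, seed = 33)
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  items <- simulate_items(ph, cfg)
  expect_true(all(unlist(items[pedvar:::.item_cols()]) %in% 0:2))
  scored <- score_phenotypes(items)
  ## no missingness: score equals the direct item sum
  direct_na <- rowSums(items[, paste0("na", 1:6)])
  m <- match(scored$individual_id, items$individual_id)
  expect_equal(scored$na, unname(direct_na[m]))
  ## injected missingness exercises the imputation path
  cfg$item_missing <- 0.08
  set.seed(1)
  items2 <- simulate_items(ph, cfg)
  scored2 <- score_phenotypes(items2)
  nmiss <- rowSums(is.na(items2[, paste0("na", 1:6)]))
  expect_true(any(nmiss %in% 1:2))
  expect_true(all(is.na(scored2$na[match(items2$individual_id[nmiss >= 3],
                                         scored2$individual_id)])))
  ## scores with <=2 missing equal the person-mean computation
  i <- which(nmiss == 2)[1]
  v <- as.numeric(items2[i, paste0("na", 1:6)])
  expect_equal(scored2$na[match(items2$individual_id[i],
                                scored2$individual_id)],
               sum(v, na.rm = TRUE) * 6 / 4)
})

test_that("recovery experiment summarises bias and coverage", {
  cfg <- sim_config(n_families = 250, seed = 51)
  rec <- recovery_experiment(cfg, n_replicates = 4)
  expect_s3_class(rec, "recovery_experiment")
  expect_equal(nrow(rec$summary), 4)
  expect_named(rec$summary,
               c("component", "truth", "mean_estimate", "bias",
                 "empirical_sd", "mean_se", "coverage"))
  expect_true(all(rec$summary$coverage >= 0 & rec$summary$coverage <= 1))
  expect_output(print(rec), "replicates")
})

test_that("fitting AE to an ADE architecture inflates the additive estimate", {
  ## misspecification direction: dropping D loads its variance onto A
  cfg <- sim_config(n_families = 800, seed = 55)
  rec <- recovery_experiment(cfg, components = "AE", n_replicates = 3)
  a_hat <- rec$results$estimate[rec$results$component == "A"]
  expect_true(all(a_hat > cfg$sigma2["A", 1]))
})
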
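make_twin_data <- function(n_pairs, rho, seed = 1, relationship = "MZ") {
  ## n_pairs twin families with bivariate-normal pair values
  set.seed(seed)
  rows <- lapply(seq_len(n_pairs), function(i) {
    fam <- sprintf("f%04d", i)
    data.frame(
      family_id = fam,
      individual_id = paste0(fam, c(".pa", ".ma", ".t1", ".t2")),
      father_id = c(NA, NA, paste0(fam, ".pa"), paste0(fam, ".pa")),
      mother_id = c(NA, NA, paste0(fam, ".ma"), paste0(fam, ".ma")),
      sex = c("male", "female", "female", "female"),
      mz_group = c(NA, NA, if (relationship == "MZ") rep(paste0(fam, ".z"), 2)
                   else rep(NA, 2)),
      birth_year = c(NA, NA, 1980L, 1980L),
      stringsAsFactors = FALSE)
  })
  ped <- pedigree(do.call(rbind, rows))
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  z <- matrix(rnorm(2 * n_pairs), n_pairs) %*% L
  phenos <- data.frame(
    individual_id = c(sprintf("f%04d.t1", seq_len(n_pairs)),
                      sprintf("f%04d.t2", seq_len(n_pairs))),
    y = c(z[, 1], z[, 2]),
    sex = "female", age = 30,
    stringsAsFactors = FALSE)
  list(ped = ped, phenos = phenos)
}

test_that("pair extraction double-enters symmetric pairs and drops
           incomplete ones", {
  d <- make_twin_data(5, 0.5)
  d$phenos$y[d$phenos$individual_id == "f0001.t2"] <- NA
  ps <- extract_pairs(d$ped, d$phenos, "MZ", "y")
  expect_equal(ps$n, 4)                   # f0001 excluded
  expect_equal(nrow(ps$pairs), 8)         # double entry
  expect_setequal(ps$pairs$x, ps$pairs$y)
  ## sib trio -> 3 distinct pairs
  trio <- pedigree(ped_df(
    list("pa", NA, NA, "male"), list("ma", NA, NA, "female"),
    list("s1", "pa", "ma", "male", NA, 1980L),
    list("s2", "pa", "ma", "male", NA, 1983L),
    list("s3", "pa", "ma", "female", NA, 1985L)))
  ph <- data.frame(individual_id = c("s1", "s2", "s3"), y = 1:3,
                   sex = c("male", "male", "female"), age = 30)
  expect_equal(extract_pairs(trio, ph, "sib", "y")$n, 3)
})

test_that("asymmetric pairs use a fixed role order with matching mean ages", {
  ped <- mz_family()
  ph <- data.frame(individual_id = c("pa", "t1", "t2"),
                   y = c(10, 1, 2), sex = c("male", "female", "female"),
                   age = c(55, 25, 25))
  ps <- extract_pairs(ped, ph, "father-daughter", "y")
  expect_equal(ps$n, 2)
  expect_true(all(ps$pairs$id1 == "pa"))
  expect_equal(unname(ps$mean_age), c(55, 25))
})

test_that("sex strata filter pairs correctly", {
  d <- make_twin_data(6, 0.4, relationship = "DZ")
  ## flip t2 of half the families to male
  male_fams <- sprintf("f%04d", 1:3)
  d$ped$df$sex[d$ped$df$individual_id %in% paste0(male_fams, ".t2")] <- "male"
  d$phenos$sex <- d$ped$df$sex[match(d$phenos$individual_id,
                                     d$ped$df$individual_id)]
  expect_equal(extract_pairs(d$ped, d$phenos, "DZ", "y", sex = "female")$n, 3)
  expect_equal(extract_pairs(d$ped, d$phenos, "DZ", "y", sex = "opposite")$n, 3)
  expect_equal(extract_pairs(d$ped, d$phenos, "DZ", "y", sex = "male")$n, 0)
})

test_that("Pearson correlation matches the direct formula and edge cases", {
  d <- make_twin_data(20, 0.5, seed = 11)
  ps <- extract_pairs(d$ped, d$phenos, "MZ", "y")
  expect_equal(pearson_correlation(ps),
               pearson_direct(ps$pairs$x, ps$pairs$y), tolerance = 1e-12)
  ident <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3))
  expect_equal(pearson_correlation(ident), 1)
  expect_equal(pearson_correlation(data.frame(x = c(1, 2, 3),
                                              y = -c(1, 2, 3))), -1)
  expect_warning(r <- pearson_correlation(data.frame(x = rep(1, 5),
                                                     y = rnorm(5))),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("tetrachoric estimation agrees with the likelihood-grid oracle", {
  expect_equal(tetrachoric(matrix(c(25, 25, 25, 25), 2))$rho, 0,
               tolerance = 1e-4)
  perfect <- tetrachoric(matrix(c(50, 0, 0, 50), 2))
  expect_equal(perfect$rho, 1)
  expect_true(perfect$boundary)
  for (tab in list(matrix(c(40, 10, 10, 40), 2),
                   matrix(c(60, 20, 5, 15), 2))) {
    est <- tetrachoric(tab)$rho
    expect_equal(est, tetra_grid(tab), tolerance = 1e-3)
    ## transpose invariance
    expect_equal(est, tetrachoric(t(tab))$rho, tolerance = 1e-6)
  }
  expect_error(tetrachoric(matrix(c(0, 0, 30, 70), 2, byrow = TRUE)),
               "margin")
})

test_that("bootstrap intervals are reproducible and degenerate-safe", {
  d <- make_twin_data(60, 0.5, seed = 3)
  ps <- extract_pairs(d$ped, d$phenos, "MZ", "y")
  ci1 <- bootstrap_ci(ps, n_boot = 300, seed = 7)
  ci2 <- bootstrap_ci(ps, n_boot = 300, seed = 7)
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_lt(ci1$lower, ci1$estimate)
  expect_gt(ci1$upper, ci1$estimate)
  ## statistic constant under resampling -> zero-width interval
  cst <- bootstrap_ci(data.frame(x = 1:30, y = 1:30),
                      statistic = function(p) 42, n_boot = 200, seed = 1)
  expect_equal(cst$lower, cst$upper)
})

test_that("bootstrap CI coverage is near nominal for a correlation", {
  ## moderate-scale simulation check of the percentile interval
  set.seed(21)
  hits <- 0L
  n_rep <- 120
  for (r in seq_len(n_rep)) {
    L <- chol(matrix(c(1, 0.4, 0.4, 1), 2))
    z <- matrix(rnorm(2 * 120), 120) %*% L
    ci <- bootstrap_ci(data.frame(x = z[, 1], y = z[, 2]),
                       n_boot = 250, seed = r)
    if (ci$lower <= 0.4 && 0.4 <= ci$upper) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.86)
  expect_lt(hits / n_rep, 0.99)
})

test_that("twin correlations recover the generative expectation", {
  ## adult MZ twins share A + D (no household at age 30):
  ## r_MZ = (A + D) / total
  cfg <- sim_config(n_families = 1500, seed = 31,
                    p_obs_twin_pair = c(both = 1, one = 0, none = 0))
  sim <- simulate_pedigrees(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  adult <- ph$role == "twin" & ph$age > 18
  keep <- ph[ph$phenotyped & (adult | ph$role != "twin"), ]
  ps <- extract_pairs(sim$ped, keep, "MZ", "na")
  r_mz <- pearson_correlation(ps)
  th <- (0.11 + 0.28) / 0.796
  expect_lt(abs(r_mz - th), 3 / sqrt(ps$n))
  ps_dz <- extract_pairs(sim$ped, keep, "DZ", "na")
  r_dz <- pearson_correlation(ps_dz)
  th_dz <- (0.5 * 0.11 + 0.25 * 0.28) / 0.796
  expect_lt(abs(r_dz - th_dz), 3.5 / sqrt(ps_dz$n))
})

test_that("the correlation table reports strata with N and CIs", {
  d <- make_twin_data(40, 0.5, seed = 5)
  strata <- data.frame(relationship = c("MZ", "spouse"),
                       sex = c("all", "all"),
                       spouse_type = c(NA, "parents-of-twins"))
  ph <- d$phenos
  ## give parents values so the spouse stratum is populated
  extra <- data.frame(individual_id = c(sprintf("f%04d.pa", 1:40),
                                        sprintf("f%04d.ma", 1:40)),
                      y = rnorm(80), sex = rep(c("male", "female"), each = 40),
                      age = 55)
  tab <- correlation_table(d$ped, rbind(ph, extra), "y", strata = strata,
                           n_boot = 200, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n, c(40, 40))
  expect_true(all(tab$ci_lower <= tab$correlation &
                  tab$correlation <= tab$ci_upper))
})
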
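#' Extract phenotyped relative pairs
#'
#' Collects, within each family, all pairs with a given relationship label
#' (see [classify_pair()]) and complete phenotypes on the chosen measure.
#' Symmetric relationships (twin, sib, spouse) are double-entered: each pair
#' contributes both orderings to the returned table, which makes the Pearson
#' correlation invariant to within-pair ordering.  Asymmetric relationships
#' use a fixed role order (parent first; grandparent first).
#'
#' @param ped A [pedigree()].
#' @param phenos data.frame with `individual_id`, the measure column(s),
#'   and optionally `age` and `sex`.
#' @param relationship Label to extract, e.g. `"MZ"`, `"DZ"`, `"sib"`,
#'   `"spouse"`, `"father-son"`.  `"spouse"` may be refined with
#'   `spouse_type`.
#' @param measure Name of the phenotype column.
#' @param sex One of `"all"`, `"male"`, `"female"`, `"opposite"`; pairs are
#'   kept when both members match (`"opposite"` keeps mixed-sex pairs).
#' @param spouse_type For `relationship = "spouse"`: `"any"`,
#'   `"parents-of-twins"` (both members are parents of a twin) or
#'   `"twin-spouse"` (one member is a twin).
#' @return A list of class `pair_set`: `pairs` (data.frame `id1,id2,x,y`,
#'   double-entered where symmetric), `n` (number of distinct pairs),
#'   `mean_age` (per role), `relationship`, `sex`, `double_entered`.
#' @export
extract_pairs <- function(ped, phenos, relationship, measure,
                          sex = "all", spouse_type = "any") {
  stopifnot(measure %in% names(phenos))
  val <- stats::setNames(phenos[[measure]], phenos$individual_id)
  sx <- stats::setNames(as.character(phenos$sex), phenos$individual_id)
  ag <- if ("age" %in% names(phenos))
    stats::setNames(as.numeric(phenos$age), phenos$individual_id) else NULL
  symmetric <- relationship %in% c("MZ", "DZ", "sib", "spouse", "half-sib",
                                   "double-first-cousin", "first-cousin",
                                   "first-cousin-MZ-parents")
  asym_first <- c("father-son", "father-daughter", "mother-son",
                  "mother-daughter", "parent-offspring", "grandparental",
                  "avuncular")
  rows <- list()
  fam_idx <- split(seq_len(nrow(ped$df)), ped$df$family_id)
  for (fam in names(fam_idx)) {
    df <- ped$df[fam_idx[[fam]], , drop = FALSE]
    ids <- df$individual_id
    ids <- ids[ids %in% names(val)]
    if (length(ids) < 2) next
    for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
      i <- ids[a]; j <- ids[b]
      if (is.na(val[i]) || is.na(val[j])) next
      lab <- .classify_df(df, i, j)     # label is order-invariant
      if (!identical(lab, relationship)) next
      if (lab %in% asym_first) {
        ## fixed role order: parent / grandparent / aunt-uncle first
        if (!.is_senior(df, i, j)) { tmp <- i; i <- j; j <- tmp }
      }
      if (relationship == "spouse" && spouse_type != "any" &&
          !.spouse_type_ok(ped, df, i, j, spouse_type)) next
      if (!.sex_ok(sx[i], sx[j], sex)) next
      rows[[length(rows) + 1L]] <- c(i, j)
    }
  }
  if (length(rows)) {
    m <- do.call(rbind, rows)
    pairs <- data.frame(id1 = m[, 1], id2 = m[, 2],
                        x = as.numeric(val[m[, 1]]),
                        y = as.numeric(val[m[, 2]]),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(id1 = character(0), id2 = character(0),
                        x = numeric(0), y = numeric(0))
  }
  n <- nrow(pairs)
  mean_age <- if (!is.null(ag) && n)
    c(role1 = mean(ag[pairs$id1], na.rm = TRUE),
      role2 = mean(ag[pairs$id2], na.rm = TRUE)) else c(role1 = NA, role2 = NA)
  if (symmetric && n) {
    pairs <- rbind(pairs,
                   data.frame(id1 = pairs$id2, id2 = pairs$id1,
                              x = pairs$y, y = pairs$x))
  }
  structure(list(pairs = pairs, n = n, mean_age = mean_age,
                 relationship = relationship, sex = sex,
                 double_entered = symmetric),
            class = "pair_set")
}

## TRUE when i holds the senior role of an asymmetric pair: an ancestor of j,
## or a sib/co-twin of one of j's parents (avuncular)
.is_senior <- function(df, i, j) {
  ids <- df$individual_id
  anc <- function(p, q) {       # p ancestor of q (within family table)
    seen <- q
    repeat {
      r <- df[match(seen, ids), , drop = FALSE]
      par <- unique(stats::na.omit(c(r$father_id, r$mother_id)))
      if (!length(par)) return(FALSE)
      if (p %in% par) return(TRUE)
      seen <- par
    }
  }
  if (anc(i, j)) return(TRUE)
  rj <- df[match(j, ids), ]
  for (par in stats::na.omit(c(rj$father_id, rj$mother_id))) {
    rp <- df[match(par, ids), ]
    ri <- df[match(i, ids), ]
    sib <- !is.na(ri$father_id) && !is.na(rp$father_id) &&
      ri$father_id == rp$father_id && !is.na(ri$mother_id) &&
      ri$mother_id == rp$mother_id
    mz <- !is.na(ri$mz_group) && !is.na(rp$mz_group) &&
      ri$mz_group == rp$mz_group
    if (isTRUE(sib) || isTRUE(mz)) return(TRUE)
  }
  FALSE
}

.sex_ok <- function(s1, s2, sex) {
  s1 <- unname(s1); s2 <- unname(s2)
  switch(sex,
         all = TRUE,
         male = isTRUE(s1 == "male") && isTRUE(s2 == "male"),
         female = isTRUE(s1 == "female") && isTRUE(s2 == "female"),
         opposite = isTRUE(s1 != s2),
         stop("unknown sex stratum: ", sex))
}

.spouse_type_ok <- function(ped, df, i, j, spouse_type) {
  is_twin <- function(id) {
    r <- df[df$individual_id == id, ]
    if (!is.na(r$mz_group)) return(TRUE)
    ## DZ twin: full sib with identical birth year
    sibs <- df[!is.na(df$father_id) & !is.na(r$father_id) &
               df$father_id == r$father_id &
               !is.na(df$mother_id) & df$mother_id == r$mother_id &
               df$individual_id != id, ]
    nrow(sibs) > 0 && !is.na(r$birth_year) &&
      any(!is.na(sibs$birth_year) & sibs$birth_year == r$birth_year)
  }
  tw <- is_twin(i) || is_twin(j)
  switch(spouse_type,
         `twin-spouse` = tw,
         `parents-of-twins` = !tw,
         any = TRUE)
}

#' Pearson correlation of a pair set
#'
#' Product-moment correlation over the (double-entered, where applicable)
#' pair list.
#'
#' @param pairs A `pair_set` from [extract_pairs()] or a data.frame with
#'   columns `x`, `y`.
#' @return Correlation in `[-1, 1]`; `NA` with a warning if either margin
#'   has zero variance or fewer than 3 pairs are available.
#' @export
pearson_correlation <- function(pairs) {
  p <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  if (nrow(p) < 3) { warning("fewer than 3 pairs"); return(NA_real_) }
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) {
    warning("zero variance in pair values"); return(NA_real_)
  }
  stats::cor(p$x, p$y)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood correlation of a latent bivariate normal dichotomised
#' at thresholds, using the two-step estimator: thresholds fixed at the
#' normal quantiles of the margins, then the multinomial likelihood (cell
#' probabilities from bivariate-normal rectangle integrals) maximised over
#' the correlation.
#'
#' @param tab 2x2 matrix of counts (rows: variable 1 no/yes; columns:
#'   variable 2 no/yes).
#' @return List with `rho`, `threshold_row`, `threshold_col`, `boundary`
#'   (TRUE when an empty off-diagonal forces rho to a +-1 boundary).
#' @examples
#' tetrachoric(matrix(c(40, 10, 10, 40), 2))
#' @export
tetrachoric <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("tetrachoric correlation undefined: empty margin")
  n <- sum(tab)
  h <- stats::qnorm(sum(tab[2, ]) / n)   # P(row = yes)
  k <- stats::qnorm(sum(tab[, 2]) / n)
  if (tab[1, 2] == 0 && tab[2, 1] == 0)
    return(list(rho = 1, threshold_row = h, threshold_col = k,
                boundary = TRUE))
  if (tab[1, 1] == 0 && tab[2, 2] == 0)
    return(list(rho = -1, threshold_row = h, threshold_col = k,
                boundary = TRUE))
  nll <- function(r) -.tetra_loglik(tab, r, h, k)
  opt <- stats::optimize(nll, c(-0.9999, 0.9999), tol = 1e-9)
  list(rho = opt$minimum, threshold_row = h, threshold_col = k,
       boundary = abs(opt$minimum) > 0.998)
}

## multinomial log-likelihood of a 2x2 table under a latent bivariate normal
## with thresholds h (rows), k (cols) and correlation r
.tetra_loglik <- function(tab, r, h, k) {
  S <- matrix(c(1, r, r, 1), 2)
  p22 <- mvtnorm::pmvnorm(lower = c(h, k), upper = c(Inf, Inf), sigma = S)[1]
  p2r <- 1 - stats::pnorm(h)
  p2c <- 1 - stats::pnorm(k)
  p <- c(1 - p2r - p2c + p22, p2c - p22, p2r - p22, p22)  # 11,12,21,22
  p <- pmax(p, 1e-12)
  sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(p))
}

#' Percentile bootstrap confidence interval for a pair statistic
#'
#' Resamples distinct pairs (not individuals) with replacement and returns
#' the percentile interval of the statistic.  Degenerate resamples for which
#' the statistic is `NA` (for example zero variance) are skipped and
#' counted.
#'
#' @param pairs A `pair_set` or a data.frame with columns `x`, `y`.  For a
#'   double-entered `pair_set` the resampling unit is the distinct pair; the
#'   statistic sees the double-entered resample.
#' @param statistic Function of a pair data.frame returning a scalar;
#'   default [pearson_correlation()] (warnings suppressed during
#'   resampling).
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed Integer seed for reproducibility.
#' @param level Confidence level, default 0.95.
#' @return List with `lower`, `upper`, `estimate`, `n_boot`, `skipped`.
#' @export
bootstrap_ci <- function(pairs, statistic = pearson_correlation,
                         n_boot = 2000, seed = 1, level = 0.95) {
  stopifnot(n_boot >= 200)
  double <- inherits(pairs, "pair_set") && pairs$double_entered
  p <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  if (double) p <- p[seq_len(nrow(p) / 2), , drop = FALSE]
  est <- suppressWarnings(
    statistic(if (double) .double_enter(p) else p))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stat <- numeric(n_boot)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    res <- p[sample.int(nrow(p), replace = TRUE), , drop = FALSE]
    if (double) res <- .double_enter(res)
    s <- suppressWarnings(statistic(res))
    if (is.na(s)) { skipped <- skipped + 1L; stat[b] <- NA } else stat[b] <- s
  }
  if (skipped) warning(skipped, " degenerate bootstrap resample(s) skipped")
  a <- (1 - level) / 2
  q <- stats::quantile(stat, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(lower = q[1], upper = q[2], estimate = est,
       n_boot = n_boot, skipped = skipped)
}

.double_enter <- function(p)
  rbind(p, data.frame(id1 = p$id2, id2 = p$id1, x = p$y, y = p$x))

.Random.seed_save <- function()
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Familial correlation table
#'
#' Per relationship class and sex stratum: the number of distinct complete
#' pairs, mean ages per role, the correlation (Pearson for continuous
#' measures, tetrachoric for a dichotomous factor) and its bootstrap
#' confidence interval.
#'
#' @inheritParams extract_pairs
#' @param measure Phenotype column; if it is a factor or 0/1 the tetrachoric
#'   correlation of the 2x2 pair table is used.
#' @param strata data.frame with columns `relationship`, `sex` and
#'   optionally `spouse_type` defining the rows of the table; default the
#'   twin/sib/parent-offspring/spouse layout of the extended-family design.
#' @param n_boot,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return data.frame with columns `relationship`, `sex`, `n`, `mean_age1`,
#'   `mean_age2`, `correlation`, `ci_lower`, `ci_upper`.
#' @export
correlation_table <- function(ped, phenos, measure,
                              strata = default_strata(),
                              n_boot = 500, seed = 1) {
  dich <- is.factor(phenos[[measure]]) ||
    all(stats::na.omit(phenos[[measure]]) %in% 0:1)
  ph <- phenos
  if (is.factor(ph[[measure]]))
    ph[[measure]] <- as.numeric(ph[[measure]]) - 1
  out <- list()
  for (r in seq_len(nrow(strata))) {
    st <- if ("spouse_type" %in% names(strata) &&
              !is.na(strata$spouse_type[r])) strata$spouse_type[r] else "any"
    ps <- extract_pairs(ped, ph, strata$relationship[r], measure,
                        sex = strata$sex[r], spouse_type = st)
    if (ps$n >= 3) {
      stat <- if (dich) .tetra_pair_stat else pearson_correlation
      ci <- bootstrap_ci(ps, statistic = stat, n_boot = n_boot,
                         seed = seed + r)
      corr <- ci$estimate; lo <- ci$lower; hi <- ci$upper
    } else corr <- lo <- hi <- NA_real_
    out[[r]] <- data.frame(relationship = strata$relationship[r],
                           sex = strata$sex[r], n = ps$n,
                           mean_age1 = ps$mean_age[1],
                           mean_age2 = ps$mean_age[2],
                           correlation = corr, ci_lower = lo, ci_upper = hi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## tetrachoric correlation of a double-entered 0/1 pair table
.tetra_pair_stat <- function(p) {
  tab <- table(factor(p$x, 0:1), factor(p$y, 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  tetrachoric(tab)$rho
}

#' @rdname correlation_table
#' @export
default_strata <- function() {
  data.frame(
    relationship = c("MZ", "MZ", "MZ", "DZ", "DZ", "DZ", "DZ", "sib",
                     "father-son", "father-daughter", "mother-son",
                     "mother-daughter", "spouse", "spouse"),
    sex = c("all", "male", "female", "all", "male", "female", "opposite",
            "all", rep("all", 4), "all", "all"),
    spouse_type = c(rep(NA, 12), "parents-of-twins", "twin-spouse"),
    stringsAsFactors = FALSE)
}
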
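#' Kinship coefficients on a pedigree with MZ groups
#'
#' Computes the kinship coefficient phi by the standard recursion over a
#' pedigree sorted founders-first: distinct founders are unrelated,
#' `phi(i,i) = (1 + phi(father_i, mother_i)) / 2`, and for i not an ancestor
#' of j, `phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2`.  Members of
#' one MZ group are collapsed onto a single genotype node, so co-twins have
#' `phi(i,j) = phi(i,i)` and are interchangeable in every recursion involving
#' third parties.
#'
#' @param ped A [pedigree()].
#' @param i,j Individual ids (must be in the same family).
#' @return `kinship()` returns the scalar phi in `[0, 1]`;
#'   `kinship_matrix()` the full symmetric matrix for one family.
#' @examples
#' ped <- pedigree(data.frame(
#'   family_id = "f", individual_id = c("pa", "ma", "c1"),
#'   father_id = c(NA, NA, "pa"), mother_id = c(NA, NA, "ma"),
#'   sex = c("male", "female", "male")))
#' kinship(ped, "pa", "c1")  # parent-offspring: 0.25
#' @export
kinship <- function(ped, i, j) {
  fam <- .ped_row(ped, i)$family_id
  if (fam != .ped_row(ped, j)$family_id) return(0)
  K <- kinship_matrix(ped, fam)
  K[i, j]
}

#' @param family A family id.
#' @rdname kinship
#' @export
kinship_matrix <- function(ped, family) {
  .kin_df(.ped_family(ped, family))
}

.kin_df <- function(df) {
  n <- nrow(df)
  ids <- df$individual_id
  ## genotype node of each individual: first-listed member of its MZ group
  node <- seq_len(n)
  mz <- df$mz_group
  for (g in unique(stats::na.omit(mz))) {
    m <- which(!is.na(mz) & mz == g)
    node[m] <- m[1]
  }
  fa <- match(df$father_id, ids)
  mo <- match(df$mother_id, ids)
  fa <- ifelse(is.na(fa), NA_integer_, node[fa])
  mo <- ifelse(is.na(mo), NA_integer_, node[mo])
  K <- matrix(0, n, n)
  ## rows are in topological order (pedigree() guarantees founders first)
  for (i in seq_len(n)) {
    if (node[i] != i) next            # co-twin: filled by expansion below
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      if (i > 1L) {
        j <- seq_len(i - 1L)
        kj <- 0.5 * (K[fa[i], j] + K[mo[i], j])
        K[i, j] <- kj
        K[j, i] <- kj
      }
    }
  }
  K <- K[node, node, drop = FALSE]
  dimnames(K) <- list(ids, ids)
  K
}

#' Dominance (fraternity) coefficients
#'
#' The probability Delta7 that two non-inbred individuals share both alleles
#' identical by descent: `Delta7(i,j) = phi(fi,fj) phi(mi,mj) +
#' phi(fi,mj) phi(mi,fj)` in terms of parental kinships, with
#' `Delta7(i,i) = 1` and the MZ-pair override `Delta7 = 1`.  Pairs involving
#' a founder score 0.  If the pedigree is inbred (any individual with
#' self-kinship above 1/2) the two-term formula is only an approximation and
#' a warning is raised.
#'
#' @inheritParams kinship
#' @return `dominance_coef()` a scalar in `[0, 1]`; `dominance_matrix()` the
#'   symmetric matrix for one family.
#' @export
dominance_coef <- function(ped, i, j) {
  fam <- .ped_row(ped, i)$family_id
  if (fam != .ped_row(ped, j)$family_id) return(0)
  D <- dominance_matrix(ped, fam)
  D[i, j]
}

#' @rdname dominance_coef
#' @param K Optional precomputed [kinship_matrix()] for the family.
#' @export
dominance_matrix <- function(ped, family, K = NULL) {
  .dom_df(.ped_family(ped, family), K)
}

.dom_df <- function(df, K = NULL) {
  ids <- df$individual_id
  n <- nrow(df)
  if (is.null(K)) K <- .kin_df(df)
  if (any(diag(K) > 0.5 + 1e-12))
    warning("inbred pedigree: two-term dominance formula assumes non-inbreeding")
  fa <- match(df$father_id, ids)
  mo <- match(df$mother_id, ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  nonf <- which(!is.na(fa))
  if (length(nonf)) {
    f <- fa[nonf]; m <- mo[nonf]
    D[nonf, nonf] <- K[f, f, drop = FALSE] * K[m, m, drop = FALSE] +
      K[f, m, drop = FALSE] * K[m, f, drop = FALSE]
  }
  diag(D) <- 1
  mz <- df$mz_group
  for (g in unique(stats::na.omit(mz))) {
    m <- which(!is.na(mz) & mz == g)
    D[m, m] <- 1
  }
  D
}

## spouse pairs within one family table: declared spouse_of links plus pairs
## inferred from shared offspring; returns 2-column matrix of row indices
.spouse_pairs <- function(df) {
  ids <- df$individual_id
  out <- matrix(integer(0), ncol = 2)
  sp <- which(!is.na(df$spouse_of))
  for (i in sp) {
    j <- match(df$spouse_of[i], ids)
    if (!is.na(j)) out <- rbind(out, sort(c(i, j)))
  }
  kid <- !is.na(df$father_id) & !is.na(df$mother_id)
  if (any(kid)) {
    pp <- unique(df[kid, c("father_id", "mother_id")])
    fa <- match(pp$father_id, ids); mo <- match(pp$mother_id, ids)
    ok <- !is.na(fa) & !is.na(mo)
    out <- rbind(out, t(apply(cbind(fa[ok], mo[ok]), 1, sort)))
  }
  unique(out)
}

#' Household sharing matrix
#'
#' Partitions the members of each family into household groups following the
#' co-residence rule used for extended twin pedigrees: spouses share a
#' household, and parents share with their offspring while the offspring are
#' not older than 18.  Each spouse pair seeds a group; offspring aged 18 or
#' younger join their parents' group (and hence each other); an individual
#' who has a spouse group of their own belongs to it rather than to the
#' parental group (spouse group takes precedence).  Individuals with unknown
#' age are treated as adults.  The grouping is a partition, so the matrix is
#' block-diagonal with blocks of ones (and therefore positive
#' semi-definite).
#'
#' @inheritParams kinship
#' @param family Family id.
#' @param ages Named numeric vector of ages in years (names are individual
#'   ids); individuals absent from `ages` are treated as adults.
#' @return Symmetric 0/1 matrix with 1 on the diagonal; attribute `"group"`
#'   holds the integer group index per individual.
#' @export
household_matrix <- function(ped, family, ages = NULL) {
  .house_df(.ped_family(ped, family), ages)
}

.house_df <- function(df, ages = NULL) {
  ids <- df$individual_id
  n <- nrow(df)
  age <- rep(NA_real_, n)
  if (!is.null(ages)) {
    m <- match(ids, names(ages))
    age[!is.na(m)] <- as.numeric(ages[m[!is.na(m)]])
  }
  grp <- seq_len(n)                       # singleton groups to start
  sp <- .spouse_pairs(df)
  in_spouse_group <- rep(FALSE, n)
  if (nrow(sp)) {
    for (r in seq_len(nrow(sp))) {        # union spouse pairs
      g <- grp[sp[r, ]]
      grp[grp == g[2]] <- g[1]
      in_spouse_group[sp[r, ]] <- TRUE
    }
  }
  ## offspring <= 18 join the parents' group unless they head a spouse group
  fa <- match(df$father_id, ids); mo <- match(df$mother_id, ids)
  minor <- !is.na(age) & age <= 18
  for (i in which(minor)) {
    if (in_spouse_group[i]) next          # precedence: own spouse group wins
    p <- c(fa[i], mo[i]); p <- p[!is.na(p)]
    if (length(p)) grp[i] <- grp[p[1]]
  }
  H <- outer(grp, grp, "==") + 0
  dimnames(H) <- list(ids, ids)
  attr(H, "group") <- stats::setNames(match(grp, unique(grp)), ids)
  H
}

#' Relationship matrices for variance-component modelling
#'
#' For each family returns the additive matrix (twice the kinship, entries in
#' `[0, 2]`, diagonal 1 for non-inbred individuals), the dominance
#' (fraternity) matrix Delta7 and the household indicator matrix.
#'
#' @inheritParams household_matrix
#' @param families Families to include (default all).
#' @return A named list over families; each element is a list of class
#'   `relmat` with `ids`, `additive`, `dominance`, `household`.
#' @examples
#' ped <- pedigree(data.frame(
#'   family_id = "f", individual_id = c("pa", "ma", "t1", "t2"),
#'   father_id = c(NA, NA, "pa", "pa"), mother_id = c(NA, NA, "ma", "ma"),
#'   sex = c("male", "female", "male", "male"),
#'   mz_group = c(NA, NA, "g", "g")))
#' relationship_matrices(ped)[["f"]]$additive
#' @export
relationship_matrices <- function(ped, ages = NULL, families = NULL) {
  idx <- split(seq_len(nrow(ped$df)), ped$df$family_id)
  if (!is.null(families)) idx <- idx[as.character(families)]
  out <- lapply(idx, function(i) {
    df <- ped$df[i, , drop = FALSE]
    K <- .kin_df(df)
    structure(list(ids = colnames(K),
                   additive = 2 * K,
                   dominance = .dom_df(df, K),
                   household = .house_df(df, ages)),
              class = "relmat")
  })
  out
}

#' Export relationship matrices as a wide TSV
#'
#' One row per ordered pair within each family with the additive, dominance
#' and household coefficients.
#'
#' @param rmats Result of [relationship_matrices()].
#' @param path Output TSV path.
#' @export
write_relmat <- function(rmats, path) {
  rows <- lapply(names(rmats), function(fam) {
    rm <- rmats[[fam]]
    n <- length(rm$ids)
    ij <- which(upper.tri(rm$additive, diag = TRUE), arr.ind = TRUE)
    data.frame(family_id = fam,
               id1 = rm$ids[ij[, 1]], id2 = rm$ids[ij[, 2]],
               additive = rm$additive[ij], dominance = rm$dominance[ij],
               household = rm$household[ij])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify the relationship of a pair
#'
#' Returns a deterministic relationship label with priority
#' MZ > parent-offspring > DZ/full-sib > half-sib > grandparental >
#' avuncular > double-first-cousin > first-cousin(-MZ-parents) > spouse >
#' other.  Full sibs with the same known birth year are labelled `"DZ"`,
#' otherwise `"sib"`; parent-offspring labels carry the sexes
#' (`"father-son"` etc. when both sexes are known).
#'
#' @inheritParams kinship
#' @return A character label, one of `"MZ"`, `"DZ"`, `"sib"`,
#'   `"father-son"`, `"father-daughter"`, `"mother-son"`,
#'   `"mother-daughter"`, `"parent-offspring"`, `"half-sib"`,
#'   `"grandparental"`, `"avuncular"`, `"double-first-cousin"`,
#'   `"first-cousin-MZ-parents"`, `"first-cousin"`, `"spouse"`, `"other"`.
#' @export
classify_pair <- function(ped, i, j) {
  ri <- .ped_row(ped, i); rj <- .ped_row(ped, j)
  if (ri$family_id != rj$family_id) return("other")
  .classify_df(.ped_family(ped, ri$family_id), i, j)
}

.classify_df <- function(df, i, j) {
  ids <- df$individual_id
  a <- match(i, ids); b <- match(j, ids)
  fa <- match(df$father_id, ids); mo <- match(df$mother_id, ids)
  mz <- df$mz_group
  same_mz <- function(p, q) !is.na(mz[p]) && !is.na(mz[q]) && mz[p] == mz[q]
  if (same_mz(a, b)) return("MZ")
  parent_of <- function(p, q)                       # p parent of q
    (!is.na(fa[q]) && fa[q] == p) || (!is.na(mo[q]) && mo[q] == p)
  if (parent_of(a, b) || parent_of(b, a)) {
    p <- if (parent_of(a, b)) a else b
    o <- if (parent_of(a, b)) b else a
    ps <- df$sex[p]; os <- df$sex[o]
    if (!is.na(ps) && !is.na(os))
      return(paste0(ifelse(ps == "male", "father", "mother"), "-",
                    ifelse(os == "male", "son", "daughter")))
    return("parent-offspring")
  }
  shared <- sum(!is.na(fa[a]) && !is.na(fa[b]) && fa[a] == fa[b],
                !is.na(mo[a]) && !is.na(mo[b]) && mo[a] == mo[b])
  if (shared == 2) {
    by <- df$birth_year[c(a, b)]
    if (!anyNA(by) && by[1] == by[2]) return("DZ")
    return("sib")
  }
  if (shared == 1) return("half-sib")
  grand <- function(p, q) {                         # p grandparent of q
    for (par in c(fa[q], mo[q])) if (!is.na(par) && parent_of(p, par))
      return(TRUE)
    FALSE
  }
  if (grand(a, b) || grand(b, a)) return("grandparental")
  full_sibs <- function(p, q)
    !is.na(fa[p]) && !is.na(fa[q]) && !is.na(mo[p]) && !is.na(mo[q]) &&
      fa[p] == fa[q] && mo[p] == mo[q] && p != q
  avunc <- function(p, q) {                         # p sib of a parent of q
    for (par in c(fa[q], mo[q])) if (!is.na(par) &&
        (full_sibs(p, par) || same_mz(p, par))) return(TRUE)
    FALSE
  }
  if (avunc(a, b) || avunc(b, a)) return("avuncular")
  if (!is.na(fa[a]) && !is.na(fa[b])) {
    ## linking-parent sibships on the two sides
    link <- function(p, q) (full_sibs(p, q) || same_mz(p, q))
    ff <- link(fa[a], fa[b]); mm <- link(mo[a], mo[b])
    fm <- link(fa[a], mo[b]); mf <- link(mo[a], fa[b])
    nlinks <- sum(ff, mm, fm, mf)
    if (nlinks >= 2) return("double-first-cousin")
    if (nlinks == 1) {
      mz_link <- (ff && same_mz(fa[a], fa[b])) || (mm && same_mz(mo[a], mo[b])) ||
                 (fm && same_mz(fa[a], mo[b])) || (mf && same_mz(mo[a], fa[b]))
      return(if (mz_link) "first-cousin-MZ-parents" else "first-cousin")
    }
  }
  sp <- .spouse_pairs(df)
  if (nrow(sp) && any(sp[, 1] == min(a, b) & sp[, 2] == max(a, b)))
    return("spouse")
  "other"
}
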
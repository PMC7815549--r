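#' Construct and validate a pedigree
#'
#' Builds a validated pedigree object from a table of individuals with parent
#' links, monozygotic (MZ) multiple-group labels and optional declared spouse
#' links.  Individuals sharing an `mz_group` label are treated as genetically
#' identical multiples throughout all relatedness computations.
#'
#' Validation enforces: unique individual ids; both parents present or both
#' absent (a single known parent is repaired by inserting a placeholder
#' founder, with a message); all referenced parents exist as records (missing
#' ones are inserted as founders); acyclic parentage; and identical parents
#' for all members of an MZ group.
#'
#' @param x A data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex` and optionally `mz_group`, `birth_year`,
#'   `spouse_of`.  Missing links may be coded `NA`, `""` or `"0"`.
#' @param null_token Token(s) denoting a missing parent/link in addition to
#'   `NA` and the empty string.
#' @return An object of class `pedigree`: a list with elements
#'   `df` (the canonical record table, placeholder founders included, in
#'   topological order with founders first) and `repairs` (character log of
#'   repairs applied).
#' @examples
#' ped <- pedigree(data.frame(
#'   family_id = "f1",
#'   individual_id = c("pa", "ma", "t1", "t2"),
#'   father_id = c(NA, NA, "pa", "pa"),
#'   mother_id = c(NA, NA, "ma", "ma"),
#'   sex = c("male", "female", "female", "female"),
#'   mz_group = c(NA, NA, "mz1", "mz1")))
#' summary(ped)
#' @export
pedigree <- function(x, null_token = "0") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("pedigree table lacks required column(s): ", paste(miss, collapse = ", "))
  for (opt in c("mz_group", "birth_year", "spouse_of"))
    if (is.null(x[[opt]])) x[[opt]] <- NA
  canon <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & (v %in% null_token | trimws(v) == "")] <- NA
    v
  }
  df <- data.frame(
    family_id     = as.character(x$family_id),
    individual_id = as.character(x$individual_id),
    father_id     = canon(x$father_id),
    mother_id     = canon(x$mother_id),
    sex           = tolower(canon(x$sex)),
    mz_group      = canon(x$mz_group),
    birth_year    = suppressWarnings(as.integer(canon(x$birth_year))),
    spouse_of     = canon(x$spouse_of),
    stringsAsFactors = FALSE)
  if (anyNA(df$individual_id)) stop("missing individual_id")
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup))
    stop("duplicate individual_id: ", paste(unique(dup), collapse = ", "))
  bad_sex <- !is.na(df$sex) & !df$sex %in% c("male", "female", "m", "f", "1", "2")
  if (any(bad_sex)) stop("unrecognised sex code: ", df$sex[bad_sex][1])
  df$sex[df$sex %in% c("m", "1")] <- "male"
  df$sex[df$sex %in% c("f", "2")] <- "female"

  repairs <- character(0)

  ## referenced but unlisted parents become founder records
  ref_fa <- setdiff(stats::na.omit(df$father_id), df$individual_id)
  ref_mo <- setdiff(stats::na.omit(df$mother_id), df$individual_id)
  if (length(ref_fa) || length(ref_mo)) {
    fam_of <- function(ids, col) vapply(ids, function(id)
      df$family_id[!is.na(df[[col]]) & df[[col]] == id][1], "")
    add <- data.frame(
      family_id = c(fam_of(ref_fa, "father_id"), fam_of(ref_mo, "mother_id")),
      individual_id = c(ref_fa, ref_mo),
      father_id = NA_character_, mother_id = NA_character_,
      sex = c(rep("male", length(ref_fa)), rep("female", length(ref_mo))),
      mz_group = NA_character_, birth_year = NA_integer_,
      spouse_of = NA_character_, stringsAsFactors = FALSE)
    df <- rbind(df, add)
    repairs <- c(repairs, paste0("inserted founder record for referenced parent ",
                                 add$individual_id))
  }

  ## single known parent: insert a placeholder founder for the other
  single <- xor(is.na(df$father_id), is.na(df$mother_id))
  if (any(single)) {
    for (i in which(single)) {
      if (is.na(df$father_id[i])) {
        ph <- paste0(df$individual_id[i], ".pf")
        df$father_id[i] <- ph; sex <- "male"
      } else {
        ph <- paste0(df$individual_id[i], ".pm")
        df$mother_id[i] <- ph; sex <- "female"
      }
      df <- rbind(df, data.frame(
        family_id = df$family_id[i], individual_id = ph,
        father_id = NA_character_, mother_id = NA_character_, sex = sex,
        mz_group = NA_character_, birth_year = NA_integer_,
        spouse_of = NA_character_, stringsAsFactors = FALSE))
      repairs <- c(repairs, paste0("single known parent for ",
                                   df$individual_id[i],
                                   ": placeholder founder ", ph, " added"))
    }
    message(sum(single), " record(s) had a single known parent; ",
            "placeholder founders inserted")
  }

  df <- .topo_sort(df)

  ## MZ groups must share both parents
  for (g in unique(stats::na.omit(df$mz_group))) {
    m <- df[!is.na(df$mz_group) & df$mz_group == g, ]
    if (length(unique(paste(m$father_id, m$mother_id))) != 1L)
      stop("mz_group '", g, "' members do not share the same parents")
    if (length(unique(m$family_id)) != 1L)
      stop("mz_group '", g, "' spans multiple families")
  }

  structure(list(df = df, repairs = repairs), class = "pedigree")
}

## Kahn topological sort, founders first; errors with a cycle path.
.topo_sort <- function(df) {
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$individual_id)
  fa <- idx[df$father_id]; mo <- idx[df$mother_id]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) if (!is.na(p)) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    stop("parentage cycle detected involving: ",
         paste(df$individual_id[left], collapse = " -> "))
  }
  df[ord, , drop = FALSE]
}

#' Read / write pedigree CSV files
#'
#' The on-disk dialect has one row per individual with columns
#' `family_id,individual_id,father_id,mother_id,sex,mz_group,birth_year`
#' (optionally `spouse_of`); missing links are written as `0`.
#'
#' @param path File path.
#' @param ... Passed on to [pedigree()].
#' @return `read_pedigree()` returns a `pedigree`; `write_pedigree()` returns
#'   `path` invisibly.
#' @export
read_pedigree <- function(path, ...) {
  pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"), ...)
}

#' @param ped A `pedigree`.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  df <- ped$df
  for (col in c("father_id", "mother_id", "mz_group", "spouse_of"))
    df[[col]][is.na(df[[col]])] <- "0"
  df$birth_year[is.na(df$birth_year)] <- "0"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$df), "individuals in",
      length(unique(x$df$family_id)), "families\n")
  if (length(x$repairs)) cat("  repairs applied:", length(x$repairs), "\n")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  df <- object$df
  founders <- is.na(df$father_id) & is.na(df$mother_id)
  cat("pedigree:", nrow(df), "individuals,",
      length(unique(df$family_id)), "families,",
      sum(founders), "founders,",
      length(unique(stats::na.omit(df$mz_group))), "MZ groups\n")
  if (length(object$repairs)) {
    cat("repairs:\n")
    for (r in object$repairs) cat("  -", r, "\n")
  }
  invisible(df)
}

## internal accessors -------------------------------------------------------

.ped_families <- function(ped) unique(ped$df$family_id)

.ped_family <- function(ped, fam) ped$df[ped$df$family_id == fam, , drop = FALSE]

.ped_row <- function(ped, id) {
  i <- match(id, ped$df$individual_id)
  if (is.na(i)) stop("individual '", id, "' not in pedigree")
  ped$df[i, , drop = FALSE]
}
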
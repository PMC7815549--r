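#' Score a 6-item proxy subscale
#'
#' Sums six 3-point (0/1/2) items.  If one or two items are missing they are
#' replaced by the person mean of the observed items of that subscale before
#' summing; with three or more missing the subscale score is missing.
#'
#' @param items Numeric vector of length 6 with values in `{0, 1, 2}` or
#'   `NA`.
#' @return The subscale score in `[0, 12]`, or `NA`.
#' @examples
#' score_subscale(c(1, 1, 1, 1, 1, 1))        # 6
#' score_subscale(c(2, 2, 2, 2, NA, NA))      # 12 (person-mean imputation)
#' score_subscale(c(0, 1, NA, NA, NA, 2))     # NA (3+ missing)
#' @export
score_subscale <- function(items) {
  if (length(items) != 6L) stop("a subscale has exactly 6 items")
  obs <- items[!is.na(items)]
  if (any(!obs %in% 0:2)) stop("item values must be 0, 1, 2 or NA")
  if (length(obs) < 4L) return(NA_real_)
  sum(obs) + (6L - length(obs)) * mean(obs)
}

#' Select the survey wave to score
#'
#' Picks, per individual, the wave with the most complete answers on the
#' twelve proxy items; ties are broken by the number of other relatives in
#' the individual's pedigree with data at that wave, then by the earliest
#' wave.
#'
#' @param waves A data.frame of one individual's waves with columns `wave`
#'   and the twelve item columns `na1..na6`, `si1..si6`.
#' @param relatives Optional named numeric vector: per wave, the count of
#'   relatives with data.
#' @return The selected value of `waves$wave`, or `NA` if every wave has all
#'   twelve items missing.
#' @export
select_wave <- function(waves, relatives = NULL) {
  if (nrow(waves) == 0L) return(NA)
  cols <- .item_cols()
  comp <- rowSums(!is.na(as.matrix(waves[, cols])))
  if (all(comp == 0L)) return(NA)
  rel <- rep(0, nrow(waves))
  if (!is.null(relatives)) {
    m <- match(as.character(waves$wave), names(relatives))
    rel[!is.na(m)] <- relatives[m[!is.na(m)]]
  }
  ord <- order(-comp, -rel, as.character(waves$wave))
  waves$wave[ord[1]]
}

.item_cols <- function() c(paste0("na", 1:6), paste0("si", 1:6))

#' Fill missing items from an individual's other waves
#'
#' Copies each missing item of the target wave from the most recent other
#' wave in which that item was answered.  Items missing in every wave are
#' left for the person-mean rule of [score_subscale()].
#'
#' @param target One-row data.frame (the selected wave).
#' @param history data.frame of the individual's other waves (same columns).
#' @return The target row with items filled where possible.
#' @export
cross_wave_impute <- function(target, history) {
  if (nrow(history) == 0L) return(target)
  history <- history[order(as.character(history$wave), decreasing = TRUE), ,
                     drop = FALSE]
  for (col in .item_cols()) {
    if (!is.na(target[[col]])) next
    v <- history[[col]]
    v <- v[!is.na(v)]
    if (length(v)) target[[col]] <- v[1]
  }
  target
}

#' Dichotomous Type D classification
#'
#' Type D requires both negative affectivity (NA) and social inhibition (SI)
#' at or above the cut-off.  If one subscale is missing while the other is
#' below the cut-off the individual is classified non-Type D (Type D is
#' already excluded); if the observed subscale is at or above the cut-off
#' the classification is missing.
#'
#' @param na,si Numeric subscale scores (vectorised), `NA` allowed.
#' @param cutoff Cut-off applied to both subscales (default 3, the validated
#'   ASEBA proxy cut-off).
#' @return Factor with levels `"no"`, `"yes"` (and `NA`).
#' @export
classify_type_d <- function(na, si, cutoff = 3) {
  if (any(stats::na.omit(c(na, si)) < 0)) stop("negative subscale score")
  both <- !is.na(na) & !is.na(si)
  out <- rep(NA_character_, length(na))
  out[both] <- ifelse(na[both] >= cutoff & si[both] >= cutoff, "yes", "no")
  one <- xor(is.na(na), is.na(si))
  obs <- ifelse(is.na(na), si, na)
  out[one & obs < cutoff] <- "no"       # cannot reach Type D any more
  factor(out, levels = c("no", "yes"))
}

#' Rank-based inverse normal transformation
#'
#' Maps a skewed trait onto standard-normal quantiles using Blom offsets:
#' `qnorm((rank - 3/8) / (n + 1/4))` with ties averaged; `NA`s are
#' preserved.
#'
#' @param x Numeric vector (with `NA`s).
#' @return Transformed vector, mean approximately 0, invariant to strictly
#'   monotone transforms of `x`.
#' @export
inverse_normal <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2L) stop("need at least 2 non-missing values")
  if (length(unique(x[obs])) == 1L) {
    warning("constant input: inverse normal transform returns zeros")
    x[obs] <- 0
    return(x)
  }
  r <- rank(x[obs], ties.method = "average")
  x[obs] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  x
}

#' Score proxy phenotypes from multi-wave item data
#'
#' End-to-end scoring: per individual, select the wave
#' ([select_wave()]), fill up to two missing items per subscale from other
#' waves ([cross_wave_impute()]), score NA and SI with the person-mean rule
#' ([score_subscale()]), form the continuous NAxSI product and the
#' dichotomous Type D classification ([classify_type_d()]).
#'
#' @param items data.frame in wide wave format: columns `individual_id`,
#'   `wave`, `na1..na6`, `si1..si6`, `age_at_survey`, `sex`.
#' @param relatives Optional list: per individual id, a named vector of
#'   relative-with-data counts per wave (for the tie-break).
#' @param cutoff Type D cut-off, default 3.
#' @return data.frame with one row per individual: `individual_id`, `na`,
#'   `si`, `naxsi`, `type_d`, `age`, `sex`, `wave`.
#' @export
score_phenotypes <- function(items, relatives = NULL, cutoff = 3) {
  stopifnot(all(c("individual_id", "wave", .item_cols()) %in% names(items)))
  out <- lapply(split(items, items$individual_id), function(w) {
    id <- w$individual_id[1]
    sel <- select_wave(w, relatives[[id]])
    if (is.na(sel))
      return(data.frame(individual_id = id, na = NA_real_, si = NA_real_,
                        naxsi = NA_real_, type_d = NA_character_,
                        age = NA_real_, sex = NA_character_, wave = NA,
                        stringsAsFactors = FALSE))
    tgt <- w[match(sel, w$wave), , drop = FALSE]
    tgt <- cross_wave_impute(tgt, w[w$wave != sel, , drop = FALSE])
    na <- score_subscale(as.numeric(tgt[1, paste0("na", 1:6)]))
    si <- score_subscale(as.numeric(tgt[1, paste0("si", 1:6)]))
    data.frame(individual_id = id, na = na, si = si, naxsi = na * si,
               type_d = NA_character_,
               age = if ("age_at_survey" %in% names(tgt))
                 as.numeric(tgt$age_at_survey[1]) else NA_real_,
               sex = if ("sex" %in% names(tgt))
                 as.character(tgt$sex[1]) else NA_character_,
               wave = sel, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$type_d <- classify_type_d(res$na, res$si, cutoff)
  res
}

#' Canonical ASEBA proxy item order
#'
#' The mapping from the scored column positions `na1..na6` / `si1..si6` to
#' the ASEBA item codes used by the 12-item Type D proxy.
#'
#' @return Named character vector (names are column positions).
#' @export
aseba_items <- function() {
  c(na1 = "ASEBA103", na2 = "ASEBA112", na3 = "ASEBA50",
    na4 = "ASEBA45",  na5 = "ASEBA115", na6 = "ASEBA87",
    si1 = "ASEBA75",  si2 = "ASEBA67",  si3 = "ASEBA69",
    si4 = "ASEBA42",  si5 = "ASEBA111", si6 = "ASEBA48")
}

#' Read long-format item responses
#'
#' Converts a long CSV (`individual_id, wave, item_code, value`, plus
#' optional `age_at_survey`, `sex`) into the wide wave format used by
#' [score_phenotypes()], mapping item codes via [aseba_items()].
#'
#' @param path CSV path.
#' @return Wide-format data.frame.
#' @export
read_items <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "wave", "item_code", "value") %in%
                names(long)))
  map <- aseba_items()
  long$col <- names(map)[match(long$item_code, map)]
  if (anyNA(long$col))
    stop("unknown item_code: ",
         paste(unique(long$item_code[is.na(long$col)]), collapse = ", "))
  keys <- unique(long[, c("individual_id", "wave")])
  wide <- keys
  for (col in .item_cols()) wide[[col]] <- NA_real_
  for (extra in c("age_at_survey", "sex"))
    if (extra %in% names(long)) wide[[extra]] <- NA
  ki <- paste(long$individual_id, long$wave)
  kw <- paste(keys$individual_id, keys$wave)
  rows <- match(ki, kw)
  for (i in seq_len(nrow(long))) {
    wide[rows[i], long$col[i]] <- long$value[i]
    for (extra in c("age_at_survey", "sex"))
      if (extra %in% names(long)) wide[rows[i], extra] <- long[[extra]][i]
  }
  wide
}
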
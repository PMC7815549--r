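# Fixture pedigrees used across the test files.  All are built in code.

ped_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    # r: id, father, mother, sex, mz (optional), by (optional)
    data.frame(individual_id = r[[1]],
               father_id = r[[2]], mother_id = r[[3]], sex = r[[4]],
               mz_group = if (length(r) >= 5) r[[5]] else NA,
               birth_year = if (length(r) >= 6) r[[6]] else NA,
               stringsAsFactors = FALSE)
  }))
  df$family_id <- "f1"
  df
}

# founder couple + MZ twin pair (+ optional sib)
mz_family <- function(sib = FALSE) {
  rows <- list(
    list("pa", NA, NA, "male"), list("ma", NA, NA, "female"),
    list("t1", "pa", "ma", "female", "g1", 1984L),
    list("t2", "pa", "ma", "female", "g1", 1984L))
  if (sib) rows <- c(rows, list(list("s1", "pa", "ma", "male", NA, 1980L)))
  pedigree(do.call(ped_df, rows))
}

dz_family <- function() {
  pedigree(ped_df(
    list("pa", NA, NA, "male"), list("ma", NA, NA, "female"),
    list("t1", "pa", "ma", "male", NA, 1984L),
    list("t2", "pa", "ma", "female", NA, 1984L)))
}

# three generations: grandparents, two married sibs, cousins; also provides
# avuncular and grandparental pairs
three_gen <- function() {
  pedigree(ped_df(
    list("gp", NA, NA, "male"), list("gm", NA, NA, "female"),
    list("u1", "gp", "gm", "male", NA, 1950L),
    list("u2", "gp", "gm", "female", NA, 1953L),
    list("w1", NA, NA, "female"), list("h2", NA, NA, "male"),
    list("c1", "u1", "w1", "male", NA, 1980L),
    list("c2", "h2", "u2", "female", NA, 1982L)))
}

# two full-sib pairs intermarrying crosswise -> double first cousins
dfc_family <- function() {
  pedigree(ped_df(
    list("a1", NA, NA, "male"), list("a2", NA, NA, "female"),
    list("b1", NA, NA, "male"), list("b2", NA, NA, "female"),
    list("s1", "a1", "a2", "male", NA, 1950L),
    list("s2", "a1", "a2", "female", NA, 1952L),
    list("r1", "b1", "b2", "female", NA, 1951L),
    list("r2", "b1", "b2", "male", NA, 1953L),
    list("c1", "s1", "r1", "male", NA, 1980L),
    list("c2", "r2", "s2", "female", NA, 1981L)))
}

# MZ twin mothers married to unrelated men -> cousins sharing a "parent"
# genotype
mzparent_family <- function() {
  pedigree(ped_df(
    list("gp", NA, NA, "male"), list("gm", NA, NA, "female"),
    list("m1", "gp", "gm", "female", "z", 1955L),
    list("m2", "gp", "gm", "female", "z", 1955L),
    list("h1", NA, NA, "male"), list("h2", NA, NA, "male"),
    list("k1", "h1", "m1", "male", NA, 1980L),
    list("k2", "h2", "m2", "female", NA, 1981L)))
}

halfsib_family <- function() {
  pedigree(ped_df(
    list("pa", NA, NA, "male"),
    list("m1", NA, NA, "female"), list("m2", NA, NA, "female"),
    list("h1", "pa", "m1", "male", NA, 1980L),
    list("h2", "pa", "m2", "female", NA, 1983L)))
}

# a larger non-inbred pedigree for oracle-equivalence checks: three founder
# couples, an MZ pair, sibling intermarriages and three generations; every
# mating is between genetically unrelated partners
big_family <- function() {
  pedigree(ped_df(
    list("f1", NA, NA, "male"), list("f2", NA, NA, "female"),
    list("f3", NA, NA, "male"), list("f4", NA, NA, "female"),
    list("f5", NA, NA, "male"), list("f6", NA, NA, "female"),
    list("h",  NA, NA, "male"),
    list("a", "f1", "f2", "male", NA, 1950L),
    list("b", "f1", "f2", "female", NA, 1952L),
    list("c", "f3", "f4", "male", "mzc", 1951L),
    list("d", "f3", "f4", "male", "mzc", 1951L),
    list("e", "f5", "f6", "female", NA, 1953L),
    list("g", "f5", "f6", "female", NA, 1955L),
    list("p1", "c", "e", "male", NA, 1975L),
    list("p2", "c", "e", "female", NA, 1977L),
    list("q1", "d", "g", "female", NA, 1976L),
    list("x", "a", "p2", "female", NA, 2000L),
    list("y", "a", "p2", "male", NA, 2002L),
    list("z", "p1", "b", "male", NA, 2004L),
    list("w", "h", "q1", "female", NA, 2003L)))
}
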
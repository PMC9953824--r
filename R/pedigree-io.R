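#' Pedigree tables
#'
#' Pedigrees are stored as one tidy tibble with one row per family member.
#' A file may hold many families keyed by `family_id`; each family must
#' contain exactly one counselee (a female, alive, unaffected by breast
#' cancer at baseline) and every member must be the counselee or one of her
#' first- or second-degree relatives.
#'
#' On-disk dialect (exact CSV header): `family_id, member_id, father_id,
#' mother_id, sex, is_counselee, age_baseline, deceased, bc_affected,
#' bc_onset_age, oc_affected, oc_onset_age, test_brca1, test_brca2`.
#' Empty string means missing. `sex` is `F`/`M`, flags are `0`/`1`, test
#' results are `0` (untested), `1` (positive), `2` (negative).
#'
#' @name pedigree_dialect
NULL

PEDIGREE_COLS <- c("family_id", "member_id", "father_id", "mother_id", "sex",
                   "is_counselee", "age_baseline", "deceased", "bc_affected",
                   "bc_onset_age", "oc_affected", "oc_onset_age",
                   "test_brca1", "test_brca2")

#' Read pedigrees from CSV
#'
#' @param path Path to a pedigree CSV in the dialect described in
#'   [pedigree_dialect].
#' @param a_max Maximum allowed age (default 94).
#' @return A validated tibble of pedigree members (all families).
#' @export
read_pedigrees <- function(path, a_max = 94) {
  if (!file.exists(path)) {
    abort_combrisk(paste0("pedigree file not found: ", path), "combrisk_io_error")
  }
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      family_id = readr::col_character(),
      member_id = readr::col_character(),
      father_id = readr::col_character(),
      mother_id = readr::col_character(),
      sex = readr::col_character(),
      is_counselee = readr::col_integer(),
      age_baseline = readr::col_integer(),
      deceased = readr::col_integer(),
      bc_affected = readr::col_integer(),
      bc_onset_age = readr::col_integer(),
      oc_affected = readr::col_integer(),
      oc_onset_age = readr::col_integer(),
      test_brca1 = readr::col_integer(),
      test_brca2 = readr::col_integer()
    ),
    na = ""
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_combrisk(sprintf("malformed pedigree row at line %d: expected %s, got '%s'",
                           probs$row[1] + 1L, probs$expected[1], probs$actual[1]),
                   "combrisk_parse_error")
  }
  missing_cols <- setdiff(PEDIGREE_COLS, names(df))
  if (length(missing_cols) > 0) {
    abort_combrisk(paste0("pedigree header is missing columns: ",
                          paste(missing_cols, collapse = ", ")),
                   "combrisk_parse_error")
  }
  validate_pedigrees(df[PEDIGREE_COLS], a_max = a_max)
}

#' Write pedigrees to CSV
#'
#' @param peds Validated pedigree tibble.
#' @param path Output file path.
#' @return `peds`, invisibly.
#' @export
write_pedigrees <- function(peds, path) {
  readr::write_csv(peds[PEDIGREE_COLS], path, na = "")
  invisible(peds)
}

#' Validate a pedigree table
#'
#' Checks the structural and phenotype invariants: one counselee per family
#' (female, alive, breast-cancer free at baseline), acyclic parent links, 0
#' or 2 in-family parents unless a parent is marked missing, onset ages not
#' exceeding the observation age, ovarian fields missing for males, positive
#' integer ages, unique member ids, and every member within two degrees of
#' kinship of the counselee.
#'
#' @param peds A tibble in the pedigree dialect.
#' @param a_max Maximum allowed age.
#' @return The tibble, invisibly validated (returned for piping).
#' @export
validate_pedigrees <- function(peds, a_max = 94) {
  peds <- tibble::as_tibble(peds)
  fail <- function(msg) abort_combrisk(msg, "combrisk_validation_error")

  if (anyDuplicated(peds[c("family_id", "member_id")])) {
    d <- peds[duplicated(peds[c("family_id", "member_id")]), ]
    fail(sprintf("duplicate member_id '%s' within family '%s'",
                 d$member_id[1], d$family_id[1]))
  }
  if (!all(peds$sex %in% c("F", "M"))) fail("sex must be 'F' or 'M'")
  if (any(is.na(peds$age_baseline)) ||
      any(peds$age_baseline < 1 | peds$age_baseline > a_max)) {
    fail(sprintf("age_baseline must be a whole year in 1..%d for every member", a_max))
  }
  ok_onset <- function(aff, onset, age) {
    # onset required iff affected; onset <= observation age
    all(is.na(onset) | (!is.na(aff) & aff == 1L)) &&
      all(is.na(onset) | onset <= age) && all(is.na(onset) | onset >= 1)
  }
  if (!ok_onset(peds$bc_affected, peds$bc_onset_age, peds$age_baseline)) {
    fail("bc_onset_age must be in 1..age_baseline and only present for affected members")
  }
  if (!ok_onset(peds$oc_affected, peds$oc_onset_age, peds$age_baseline)) {
    fail("oc_onset_age must be in 1..age_baseline and only present for affected members")
  }
  males <- peds$sex == "M"
  if (any(!is.na(peds$oc_affected[males]) & peds$oc_affected[males] == 1L) ||
      any(!is.na(peds$oc_onset_age[males]))) {
    fail("ovarian cancer fields must be missing for males")
  }
  if (!all(peds$test_brca1 %in% c(0:2, NA)) || !all(peds$test_brca2 %in% c(0:2, NA))) {
    fail("test results must be coded 0 (untested), 1 (positive) or 2 (negative)")
  }

  for (fid in unique(peds$family_id)) {
    fam <- peds[peds$family_id == fid, ]
    cns <- which(fam$is_counselee == 1L)
    if (length(cns) != 1L) {
      fail(sprintf("family '%s' must contain exactly one counselee", fid))
    }
    cz <- fam[cns, ]
    if (cz$sex != "F" || isTRUE(cz$deceased == 1L) || isTRUE(cz$bc_affected == 1L)) {
      fail(sprintf(
        "counselee in family '%s' must be female, alive, and free of breast cancer at baseline",
        fid))
    }
    ids <- fam$member_id
    fa <- match(fam$father_id, ids)
    mo <- match(fam$mother_id, ids)
    # parent pointers that name an id must resolve within the family
    if (any(!is.na(fam$father_id) & is.na(fa)) ||
        any(!is.na(fam$mother_id) & is.na(mo))) {
      fail(sprintf("family '%s' has parent ids that do not match any member", fid))
    }
    # acyclicity via repeated leaf stripping on the parent DAG
    n <- nrow(fam)
    parents <- cbind(fa, mo)
    remaining <- rep(TRUE, n)
    repeat {
      is_leaf <- remaining & !(seq_len(n) %in% parents[remaining, ])
      if (!any(is_leaf)) break
      remaining[is_leaf] <- FALSE
    }
    if (any(remaining)) fail(sprintf("family '%s' has cyclic parent links", fid))
    deg <- relationship_degrees_one(fam)
    if (any(is.na(deg) | deg > 2L)) {
      fail(sprintf("family '%s' contains members beyond second-degree kinship of the counselee", fid))
    }
  }
  peds
}

# Degrees for every member of one family (counselee = 0).
relationship_degrees_one <- function(fam) {
  ids <- fam$member_id
  fa <- match(fam$father_id, ids)
  mo <- match(fam$mother_id, ids)
  cz <- which(fam$is_counselee == 1L)
  n <- nrow(fam)
  parents <- function(i) stats::na.omit(c(fa[i], mo[i]))
  children <- function(i) which(fa == i | mo == i)
  sibs <- function(i) {
    # full siblings share both parents; half siblings share exactly one
    out <- integer(0); half <- integer(0)
    for (j in seq_len(n)[-i]) {
      shared <- sum(c(!is.na(fa[i]) && !is.na(fa[j]) && fa[i] == fa[j],
                      !is.na(mo[i]) && !is.na(mo[j]) && mo[i] == mo[j]))
      if (shared == 2) out <- c(out, j)
      if (shared == 1) half <- c(half, j)
    }
    list(full = out, half = half)
  }
  deg <- rep(NA_integer_, n)
  deg[cz] <- 0L
  sb <- sibs(cz)
  first <- unique(c(parents(cz), children(cz), sb$full))
  deg[first] <- 1L
  second <- integer(0)
  for (p in parents(cz)) {
    second <- c(second, parents(p))                  # grandparents
    psb <- sibs(p)
    second <- c(second, psb$full, psb$half)          # aunts/uncles
  }
  for (ch in children(cz)) second <- c(second, children(ch))  # grandchildren
  second <- c(second, sb$half)                       # half-siblings
  second <- setdiff(unique(second), c(cz, first))
  deg[second] <- 2L
  deg
}

#' Kinship degree of a member relative to the counselee
#'
#' Returns 0 for the counselee, 1 for parents/full siblings/children, and 2
#' for grandparents, grandchildren, aunts/uncles, and half-siblings.
#'
#' @param peds Pedigree tibble (one or more families).
#' @param family_id Family to look in.
#' @param member_id Member of interest.
#' @return Integer degree (0, 1 or 2).
#' @export
relationship_degree <- function(peds, family_id, member_id) {
  fam <- peds[peds$family_id == family_id, ]
  if (nrow(fam) == 0) abort_combrisk("unknown family_id", "combrisk_lookup_error")
  i <- match(member_id, fam$member_id)
  if (is.na(i)) abort_combrisk("unknown member_id", "combrisk_lookup_error")
  relationship_degrees_one(fam)[i]
}

#' Count affected female first-degree relatives
#'
#' The relative-hazard model's family-history summary: the number of female
#' first-degree relatives (mother, full sisters, daughters) with breast
#' cancer. Missing breast-cancer status counts as unaffected, by convention
#' of that model.
#'
#' @param peds Pedigree tibble (one or more families).
#' @return A tibble with `family_id` and `n_affected_first_degree`.
#' @export
count_affected_first_degree <- function(peds) {
  cz <- peds[peds$is_counselee == 1L, c("family_id", "member_id", "father_id", "mother_id")]
  i <- match(peds$family_id, cz$family_id)
  cz_id <- cz$member_id[i]; cz_fa <- cz$father_id[i]; cz_mo <- cz$mother_id[i]
  eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
  is_mother <- eq(peds$member_id, cz_mo)
  is_sister <- eq(peds$father_id, cz_fa) & eq(peds$mother_id, cz_mo) &
    !eq(peds$member_id, cz_id)
  is_daughter <- eq(peds$mother_id, cz_id) | eq(peds$father_id, cz_id)
  hit <- (is_mother | is_sister | is_daughter) & peds$sex == "F" &
    !is.na(peds$bc_affected) & peds$bc_affected == 1L
  fids <- unique(peds$family_id)
  counts <- rowsum(as.integer(hit), factor(peds$family_id, levels = fids))
  tibble::tibble(family_id = fids,
                 n_affected_first_degree = as.integer(counts[, 1]))
}

#' Read a covariate table from CSV
#'
#' Columns: `family_id`, `age_menarche_cat` (0 = menarche at 14+, 1 = 12-13,
#' 2 = under 12), `age_first_birth_cat` (0 = first live birth before 20,
#' 1 = 20-24, 2 = 25-29 or nulliparous, 3 = 30+), `n_biopsies_cat` (0, 1,
#' 2 = two or more), `atypical_hyperplasia` (`no`/`yes`/`unknown`),
#' `race_label` (free label, informational).
#'
#' @param path CSV path.
#' @return A tibble of covariates.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    abort_combrisk(paste0("covariate file not found: ", path), "combrisk_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    family_id = readr::col_character(),
    age_menarche_cat = readr::col_integer(),
    age_first_birth_cat = readr::col_integer(),
    n_biopsies_cat = readr::col_integer(),
    atypical_hyperplasia = readr::col_character(),
    race_label = readr::col_character()
  ), na = "")
  validate_covariates(df)
}

validate_covariates <- function(df) {
  ok <- all(df$age_menarche_cat %in% 0:2) &&
    all(df$age_first_birth_cat %in% 0:3) &&
    all(df$n_biopsies_cat %in% 0:2) &&
    all(df$atypical_hyperplasia %in% c("no", "yes", "unknown"))
  if (!ok) abort_combrisk("covariate table has out-of-range category codes",
                          "combrisk_coding_error")
  tibble::as_tibble(df)
}
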
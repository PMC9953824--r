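# Synthetic cohort generator: counselee-centred families restricted to
# first/second-degree relatives, Hardy-Weinberg founders, Mendelian
# transmission, penetrance-driven baseline phenotypes, Gaussian birth-gap
# and death-age distributions, independent covariate sampling, and 5-year
# outcomes drawn from the penetrance-modification model.

#' Simulation configuration
#'
#' Bundles the generating process parameters. Family-structure counts,
#' covariate category probabilities and the counselee baseline-age
#' distribution are documented synthetic stand-ins for a family-history
#' enriched cohort; the birth-gap (mean 27, sd 6) and death-age (mean 80,
#' sd 15) distributions are the stated design values.
#'
#' @param mendelian [mendelian_params()] used for genotypes and baseline
#'   phenotypes.
#' @param bcrat [bcrat_params()] whose relative hazard modifies the
#'   non-carrier penetrance in outcome generation.
#' @param counselee_age_mean,counselee_age_sd,counselee_age_range Baseline
#'   age distribution of counselees (rounded truncated normal).
#' @param gap_mean,gap_sd,min_gap Parent-child age gap distribution in
#'   years; gaps below `min_gap` are resampled so parents are at least
#'   `min_gap` years older than their children.
#' @param death_mean,death_sd Death-age distribution for non-counselees
#'   (truncated positive).
#' @param n_siblings_mean,n_children_mean,n_auntuncle_mean Poisson means
#'   for sibling/child counts and aunts/uncles per parental side.
#' @param max_siblings,max_children,max_auntuncles Caps keeping family
#'   sizes at most 20.
#' @param p_menarche,p_biopsies Category probabilities for age at menarche
#'   (0/1/2) and number of biopsies (0/1/2).
#' @param p_hyperplasia Probabilities of `no`/`yes`/`unknown` atypical
#'   hyperplasia among women with at least one biopsy.
#' @param tau Outcome horizon in years (default 5).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mendelian = mendelian_params(),
                       bcrat = bcrat_params(),
                       counselee_age_mean = 47,
                       counselee_age_sd = 12,
                       counselee_age_range = c(20, 75),
                       gap_mean = 27, gap_sd = 6, min_gap = 12,
                       death_mean = 80, death_sd = 15,
                       n_siblings_mean = 2,
                       n_children_mean = 1.2,
                       n_auntuncle_mean = 1.5,
                       max_siblings = 4, max_children = 3, max_auntuncles = 3,
                       p_menarche = c(0.15, 0.50, 0.35),
                       p_biopsies = c(0.60, 0.25, 0.15),
                       p_hyperplasia = c(no = 0.82, yes = 0.08, unknown = 0.10),
                       tau = 5) {
  stopifnot(tau >= 1, abs(sum(p_menarche) - 1) < 1e-8,
            abs(sum(p_biopsies) - 1) < 1e-8,
            abs(sum(p_hyperplasia) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

rcat <- function(n, probs) {
  findInterval(stats::runif(n), cumsum(probs)) + 1L
}

#' Simulate family structures
#'
#' Generates counselee-centred family skeletons: counselee, two parents,
#' four grandparents, and sampled full siblings, children, and aunts/uncles
#' per parental side, with consistent parent links. Children's fathers are
#' not family members (they would not be blood relatives) and are recorded
#' as missing.
#'
#' @param cfg [sim_config()].
#' @param n Number of families.
#' @return A skeleton tibble with columns `family_id`, `member_id`,
#'   `father_id`, `mother_id`, `sex`, `is_counselee`, `role`.
#' @export
simulate_structure <- function(cfg, n) {
  fid <- sprintf("fam%07d", seq_len(n))
  fixed_roles <- c("cns", "f", "m", "pgf", "pgm", "mgf", "mgm")
  fixed_ids   <- c("1", "f", "m", "pgf", "pgm", "mgf", "mgm")
  fixed_fa    <- c("f", "pgf", "mgf", NA, NA, NA, NA)
  fixed_mo    <- c("m", "pgm", "mgm", NA, NA, NA, NA)
  fixed_sex   <- c("F", "M", "F", "M", "F", "M", "F")
  base <- tibble::tibble(
    family_id = rep(fid, each = 7L),
    member_id = rep(fixed_ids, n),
    father_id = rep(fixed_fa, n),
    mother_id = rep(fixed_mo, n),
    sex = rep(fixed_sex, n),
    is_counselee = rep(c(1L, rep(0L, 6)), n),
    role = rep(fixed_roles, n)
  )
  extra <- function(count, role, fa, mo) {
    tot <- sum(count)
    if (tot == 0) return(NULL)
    tibble::tibble(
      family_id = rep(fid, count),
      member_id = paste0(role, sequence(count)),
      father_id = fa, mother_id = mo,
      sex = c("F", "M")[rcat(tot, c(0.5, 0.5))],
      is_counselee = 0L,
      role = role
    )
  }
  n_sib <- pmin(stats::rpois(n, cfg$n_siblings_mean), cfg$max_siblings)
  n_kid <- pmin(stats::rpois(n, cfg$n_children_mean), cfg$max_children)
  n_pau <- pmin(stats::rpois(n, cfg$n_auntuncle_mean), cfg$max_auntuncles)
  n_mau <- pmin(stats::rpois(n, cfg$n_auntuncle_mean), cfg$max_auntuncles)
  out <- dplyr::bind_rows(
    base,
    extra(n_sib, "s", "f", "m"),
    extra(n_kid, "k", NA_character_, "1"),
    extra(n_pau, "pa", "pgf", "pgm"),
    extra(n_mau, "ma", "mgf", "mgm")
  )
  dplyr::arrange(out, .data$family_id, .data$role, .data$member_id)
}

#' Assign ages and vital status
#'
#' Draws the counselee's baseline age, then generation-by-generation
#' Gaussian parent-child birth gaps (children of the counselee are kept
#' only if already born by baseline), and death ages for non-counselees.
#' The observation age `age_baseline` is the attained age at baseline for
#' the living and the age at death for the deceased, capped at the
#' penetrance table's maximum age.
#'
#' @param skel Skeleton from [simulate_structure()].
#' @param cfg [sim_config()].
#' @return The tibble with `age_baseline` and `deceased` added.
#' @export
assign_ages <- function(skel, cfg) {
  a_max <- cfg$mendelian$a_max
  fid <- unique(skel$family_id)
  n <- length(fid)
  a0 <- round(pmin(pmax(
    stats::rnorm(n, cfg$counselee_age_mean, cfg$counselee_age_sd),
    cfg$counselee_age_range[1]), cfg$counselee_age_range[2]))
  gap <- function(m) round(rnorm_trunc(m, cfg$gap_mean, cfg$gap_sd, cfg$min_gap))
  age_f <- a0 + gap(n); age_m <- a0 + gap(n)
  age_by_role <- list(
    cns = a0, f = age_f, m = age_m,
    pgf = age_f + gap(n), pgm = age_f + gap(n),
    mgf = age_m + gap(n), mgm = age_m + gap(n)
  )
  i_fam <- match(skel$family_id, fid)
  attained <- rep(NA_real_, nrow(skel))
  for (r in names(age_by_role)) {
    rows <- skel$role == r
    attained[rows] <- age_by_role[[r]][i_fam[rows]]
  }
  # siblings and aunts/uncles relative to the younger of their two parents,
  # so every parent is at least min_gap years older than each child
  child_age <- function(ref, gaps) pmin(pmax(ref - gaps, 1), ref - cfg$min_gap)
  sib <- skel$role == "s"
  ref_sib <- pmin(age_f, age_m)
  attained[sib] <- child_age(ref_sib[i_fam[sib]], gap(sum(sib)))
  pau <- skel$role == "pa"
  ref_pau <- pmin(age_by_role$pgf, age_by_role$pgm)
  attained[pau] <- child_age(ref_pau[i_fam[pau]], gap(sum(pau)))
  mau <- skel$role == "ma"
  ref_mau <- pmin(age_by_role$mgf, age_by_role$mgm)
  attained[mau] <- child_age(ref_mau[i_fam[mau]], gap(sum(mau)))
  kid <- skel$role == "k"
  attained[kid] <- a0[i_fam[kid]] - gap(sum(kid))

  out <- skel
  out$.attained <- attained
  out <- out[!(out$role == "k" & out$.attained < 1), ]  # not yet born
  death <- round(rnorm_trunc(nrow(out), cfg$death_mean, cfg$death_sd, 1))
  death[out$is_counselee == 1L] <- Inf  # counselees are alive at baseline
  out$.death <- death
  out$deceased <- as.integer(death < out$.attained)
  out$age_baseline <- as.integer(pmin(out$.attained, death, a_max))
  out
}

# Per-gene Mendelian drop along the fixed family structure.
drop_gene <- function(ped, q) {
  n <- nrow(ped)
  copies <- rep(NA_integer_, n)
  founder <- ped$role %in% c("pgf", "pgm", "mgf", "mgm")
  copies[founder] <- stats::rbinom(sum(founder), 2, q)
  inherit <- function(child_rows, fa_copies, mo_copies) {
    stats::rbinom(length(child_rows), 1, fa_copies / 2) +
      stats::rbinom(length(child_rows), 1, mo_copies / 2)
  }
  fid <- ped$family_id
  by_role <- function(r) match(paste(unique(fid), r), paste(fid, ped$role))
  # one row per family for the fixed roles
  ufid <- unique(fid)
  idx <- function(r) match(paste0(ufid, "\r", r), paste0(fid, "\r", ped$role))
  for (spec_ in list(c("f", "pgf", "pgm"), c("m", "mgf", "mgm"))) {
    ch <- idx(spec_[1])
    copies[ch] <- inherit(ch, copies[idx(spec_[2])], copies[idx(spec_[3])])
  }
  i_fam <- match(fid, ufid)
  f_row <- idx("f")[i_fam]; m_row <- idx("m")[i_fam]
  pgf_row <- idx("pgf")[i_fam]; pgm_row <- idx("pgm")[i_fam]
  mgf_row <- idx("mgf")[i_fam]; mgm_row <- idx("mgm")[i_fam]
  cns_row <- idx("cns")[i_fam]
  grp <- function(r) which(ped$role == r)
  for (r in c("cns", "s")) {
    rows <- grp(r)
    copies[rows] <- inherit(rows, copies[f_row[rows]], copies[m_row[rows]])
  }
  rows <- grp("pa")
  copies[rows] <- inherit(rows, copies[pgf_row[rows]], copies[pgm_row[rows]])
  rows <- grp("ma")
  copies[rows] <- inherit(rows, copies[mgf_row[rows]], copies[mgm_row[rows]])
  rows <- grp("k")  # unknown co-parent: independent Hardy-Weinberg founder
  spouse <- stats::rbinom(length(rows), 2, q)
  copies[rows] <- inherit(rows, copies[cns_row[rows]], spouse)
  copies
}

#' Simulate genotypes by Mendelian inheritance
#'
#' Founders (the four grandparents, and the unobserved co-parents of the
#' counselee's children) receive Hardy-Weinberg genotypes; everyone else
#' inherits one allele per parent per gene, independently across the two
#' genes.
#'
#' @param ped Aged skeleton from [assign_ages()].
#' @param cfg [sim_config()].
#' @return The tibble with `copies_brca1`, `copies_brca2` and
#'   `carrier_class` added.
#' @export
simulate_genotypes <- function(ped, cfg) {
  ped$copies_brca1 <- drop_gene(ped, cfg$mendelian$allele_freq_brca1)
  ped$copies_brca2 <- drop_gene(ped, cfg$mendelian$allele_freq_brca2)
  ped$carrier_class <- carrier_class_of(ped$copies_brca1, ped$copies_brca2)
  ped
}

# Vectorised onset sampling from a cumulative penetrance column.
sample_onset <- function(n, Fcum) {
  u <- stats::runif(n)
  onset <- findInterval(u, Fcum) + 1L
  onset[u > Fcum[length(Fcum)]] <- NA_integer_
  onset
}

#' Simulate baseline cancer phenotypes
#'
#' For each member and cancer, draws an age of onset from the
#' genotype-specific annual penetrance (or "never affected" with the
#' complementary probability) and records the member as affected only if
#' the onset falls within the observation window, i.e. at or before
#' `age_baseline`; onsets after death are thereby recoded unaffected.
#'
#' @param ped Genotyped tibble from [simulate_genotypes()].
#' @param cfg [sim_config()].
#' @return The tibble with phenotype and (untested) test-result columns
#'   added, plus `eligible` on counselee rows (no breast cancer at
#'   baseline).
#' @export
simulate_baseline_phenotypes <- function(ped, cfg) {
  pen <- cfg$mendelian$penetrance
  n <- nrow(ped)
  onset_bc <- rep(NA_integer_, n)
  onset_oc <- rep(NA_integer_, n)
  for (cl in CARRIER_CLASSES) {
    rows_f <- which(ped$carrier_class == cl & ped$sex == "F")
    rows_m <- which(ped$carrier_class == cl & ped$sex == "M")
    if (length(rows_f)) {
      onset_bc[rows_f] <- sample_onset(length(rows_f), pen$F$breast_female[, cl])
      onset_oc[rows_f] <- sample_onset(length(rows_f), pen$F$ovarian_female[, cl])
    }
    if (length(rows_m)) {
      onset_bc[rows_m] <- sample_onset(length(rows_m), pen$F$breast_male[, cl])
    }
  }
  bc_aff <- !is.na(onset_bc) & onset_bc <= ped$age_baseline
  oc_aff <- !is.na(onset_oc) & onset_oc <= ped$age_baseline
  ped$bc_affected <- as.integer(bc_aff)
  ped$bc_onset_age <- ifelse(bc_aff, onset_bc, NA_integer_)
  ped$oc_affected <- ifelse(ped$sex == "F", as.integer(oc_aff), NA_integer_)
  ped$oc_onset_age <- ifelse(oc_aff, onset_oc, NA_integer_)
  ped$test_brca1 <- 0L
  ped$test_brca2 <- 0L
  ped
}

#' Simulate risk-factor covariates
#'
#' Menarche and biopsy categories are sampled independently from the
#' configured distributions; atypical hyperplasia is sampled among women
#' with at least one biopsy; age at first live birth and the number of
#' affected first-degree relatives are derived from the simulated family
#' history, never sampled.
#'
#' @param ped Phenotyped pedigree tibble.
#' @param cfg [sim_config()].
#' @return A covariate tibble with one row per family.
#' @export
simulate_covariates <- function(ped, cfg) {
  ufid <- unique(ped$family_id)
  n <- length(ufid)
  cns <- ped[ped$is_counselee == 1L, ]
  cns <- cns[match(ufid, cns$family_id), ]
  men <- rcat(n, cfg$p_menarche) - 1L
  bio <- rcat(n, cfg$p_biopsies) - 1L
  ah <- rep("no", n)
  has_bio <- bio > 0
  ah[has_bio] <- names(cfg$p_hyperplasia)[rcat(sum(has_bio), cfg$p_hyperplasia)]
  # age at first live birth from the oldest child's birth year
  kids <- ped[ped$role == "k", ]
  kid_age <- if (is.null(kids$.attained)) kids$age_baseline else kids$.attained
  oldest <- tapply(kid_age, kids$family_id, max)
  afb_age <- cns$age_baseline - as.integer(oldest[ufid])
  afb_cat <- dplyr::case_when(
    is.na(afb_age) ~ 2L,  # nulliparous shares the reference-adjacent category
    afb_age < 20 ~ 0L,
    afb_age < 25 ~ 1L,
    afb_age < 30 ~ 2L,
    TRUE ~ 3L
  )
  counts <- count_affected_first_degree(ped)
  nrel <- counts$n_affected_first_degree[match(ufid, counts$family_id)]
  tibble::tibble(
    family_id = ufid,
    age_menarche_cat = men,
    age_first_birth_cat = afb_cat,
    n_biopsies_cat = bio,
    atypical_hyperplasia = ah,
    n_affected_first_degree_cat = pmin(nrel, 2L),
    race_label = "synthetic"
  )
}

#' Simulate 5-year outcomes from the penetrance-modification model
#'
#' For each eligible counselee (no breast cancer at baseline), samples a
#' future age of breast-cancer onset from her true-genotype
#' penetrance-modification distribution -- the non-carrier hazard scaled by
#' her covariate relative hazard, carrier hazards unmodified -- rescaled to
#' be conditional on being unaffected at the baseline age. The tau-year
#' outcomes are not subject to censoring.
#'
#' @param ped Phenotyped pedigree tibble.
#' @param cov Covariates from [simulate_covariates()].
#' @param cfg [sim_config()].
#' @return A counselee-level tibble: `family_id`, `age_baseline`,
#'   `carrier_class` (truth), `eligible`, `event`, `onset_age`, `time`,
#'   `cause`, and the generating model's own conditional tau-year risk
#'   `p_true`.
#' @export
simulate_outcomes <- function(ped, cov, cfg) {
  pen <- cfg$mendelian$penetrance
  a_max <- pen$a_max
  tau <- cfg$tau
  cns <- ped[ped$is_counselee == 1L, ]
  cov <- cov[match(cns$family_id, cov$family_id), ]
  n <- nrow(cns)
  a0 <- cns$age_baseline
  eligible <- cns$bc_affected == 0L

  # conditional cumulative penetrance F(t) per counselee (n x a_max)
  rr <- relative_hazard(cov, cfg$bcrat)
  h0 <- pen$h$breast_female[, "none"]
  f_cal <- cfg$bcrat$f_cal
  Hmod <- pmin(rr_matrix(rr, a_max) * matrix(h0 * f_cal, n, a_max, byrow = TRUE), 1)
  noncar <- cns$carrier_class == "none"
  Fmat <- matrix(NA_real_, n, a_max)
  if (any(noncar)) {
    Fmat[noncar, ] <- 1 - t(apply(1 - Hmod[noncar, , drop = FALSE], 1, cumprod))
  }
  for (cl in c("brca1", "brca2", "both")) {
    rows <- cns$carrier_class == cl
    if (any(rows)) {
      Fmat[rows, ] <- matrix(pen$F$breast_female[, cl], sum(rows), a_max, byrow = TRUE)
    }
  }
  F_a0 <- Fmat[cbind(seq_len(n), a0)]
  F_tau <- Fmat[cbind(seq_len(n), pmin(a0 + tau, a_max))]
  p_true <- (F_tau - F_a0) / (1 - F_a0)

  # sample future onset conditional on being unaffected at a0
  u <- F_a0 + stats::runif(n) * (1 - F_a0)
  onset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!eligible[i]) next
    t_on <- findInterval(u[i], Fmat[i, ]) + 1L
    if (t_on <= a_max && u[i] <= Fmat[i, a_max]) onset[i] <- t_on
  }
  event <- !is.na(onset) & onset <= a0 + tau
  tibble::tibble(
    family_id = cns$family_id,
    age_baseline = a0,
    carrier_class = cns$carrier_class,
    eligible = eligible,
    event = ifelse(eligible, as.integer(event), NA_integer_),
    onset_age = onset,
    time = ifelse(event, onset - a0, tau),
    cause = ifelse(event, "bc", "none"),
    p_true = ifelse(eligible, p_true, NA_real_)
  )
}

#' Simulate a full cohort
#'
#' Runs the whole generating process for `n_families` families, excludes
#' counselees with breast cancer at baseline, and returns (optionally
#' writes) the pedigree and covariate tables in the package's on-disk
#' dialects together with the counselee-level outcome table and the truth
#' table used only by oracle tests.
#'
#' @param cfg [sim_config()].
#' @param n_families Number of families to generate.
#' @param seed Integer seed; the same seed and `n_families` reproduce the
#'   output exactly.
#' @param out_dir Optional directory to write `pedigrees.csv`,
#'   `covariates.csv`, `outcomes.csv`, `truth.csv`.
#' @return A list of class `combrisk_cohort` with elements `pedigrees`,
#'   `covariates`, `cohort` (eligible counselees), `truth`, and
#'   `n_excluded`.
#' @export
simulate_cohort <- function(cfg, n_families, seed, out_dir = NULL) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  ped <- simulate_structure(cfg, n_families)
  ped <- assign_ages(ped, cfg)
  ped <- simulate_genotypes(ped, cfg)
  ped <- simulate_baseline_phenotypes(ped, cfg)
  cov <- simulate_covariates(ped, cfg)
  outcomes <- simulate_outcomes(ped, cov, cfg)

  keep <- outcomes$family_id[outcomes$eligible]
  cohort <- outcomes[outcomes$eligible, ]
  peds_out <- ped[ped$family_id %in% keep, PEDIGREE_COLS]
  truth <- ped[ped$family_id %in% keep,
               c("family_id", "member_id", "copies_brca1", "copies_brca2",
                 "carrier_class")]
  cov_out <- cov[cov$family_id %in% keep, ]
  res <- structure(list(
    pedigrees = tibble::as_tibble(peds_out),
    covariates = cov_out,
    cohort = cohort,
    truth = tibble::as_tibble(truth),
    n_excluded = sum(!outcomes$eligible),
    tau = cfg$tau, seed = seed
  ), class = "combrisk_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pedigrees(res$pedigrees, file.path(out_dir, "pedigrees.csv"))
    readr::write_csv(res$covariates, file.path(out_dir, "covariates.csv"), na = "")
    readr::write_csv(res$cohort, file.path(out_dir, "outcomes.csv"), na = "")
    readr::write_csv(res$truth, file.path(out_dir, "truth.csv"), na = "")
  }
  res
}

#' @export
print.combrisk_cohort <- function(x, ...) {
  cat("<combrisk_cohort>", nrow(x$cohort), "eligible counselees (",
      x$n_excluded, "excluded ),", sum(x$cohort$event), "events within",
      x$tau, "years\n")
  invisible(x)
}
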
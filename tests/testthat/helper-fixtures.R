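# Shared fixtures: small parameter sets built in code, a random-pedigree
# generator, and a kinship-coefficient oracle.

# Penetrance table with a constant annual breast-cancer hazard per class
# (f(a) = h (1-h)^(a-1)); ovarian and male breast hazards optionally zero.
const_hazard_penetrance <- function(h = c(none = 0.01, brca1 = 0.05,
                                          brca2 = 0.03, both = 0.05),
                                    a_max = 40, h_ovarian = 0) {
  ages <- seq_len(a_max)
  f_of <- function(hz) if (hz == 0) rep(0, a_max) else hz * (1 - hz)^(ages - 1)
  mk <- function(cancer, sex, hz4) {
    tibble::tibble(age = ages, cancer = cancer, sex = sex,
                   class_none = f_of(hz4[1]), class_brca1 = f_of(hz4[2]),
                   class_brca2 = f_of(hz4[3]), class_both = f_of(hz4[4]))
  }
  penetrance_table(dplyr::bind_rows(
    mk("breast", "female", unname(h[c("none", "brca1", "brca2", "both")])),
    mk("breast", "male", rep(0, 4)),
    mk("ovarian", "female", rep(h_ovarian, 4))
  ))
}

zero_mortality <- function(a_max = 40) {
  dplyr::bind_rows(
    tibble::tibble(age = seq_len(a_max), sex = "female", hazard = 0),
    tibble::tibble(age = seq_len(a_max), sex = "male", hazard = 0)
  )
}

tiny_mendelian_params <- function(q1 = 0.05, q2 = 0.02, a_max = 40, ...) {
  mendelian_params(allele_freq_brca1 = q1, allele_freq_brca2 = q2,
                   penetrance = const_hazard_penetrance(a_max = a_max, ...),
                   mortality = zero_mortality(a_max))
}

# bcrat_params whose relative hazard is identically 1 and f_cal is 1.
neutral_bcrat_params <- function(a_max = 94, h1 = NULL, h2 = NULL) {
  coefs <- default_bcrat_coefficients()
  coefs[c("menarche", "biopsies", "first_birth", "relatives",
          "age_band2_x_biopsies", "first_birth_x_relatives")] <- 0
  coefs$ah_multiplier <- c(no = 1, yes = 1, unknown = 1)
  hz <- default_bcrat_hazards(a_max)
  hz$f_cal <- 1
  if (!is.null(h1)) hz$h1 <- h1
  if (!is.null(h2)) hz$h2 <- h2
  bcrat_params(coefficients = coefs, hazards = hz)
}

reference_covariates <- function(n = 1, family_id = paste0("f", seq_len(n))) {
  tibble::tibble(family_id = family_id,
                 age_menarche_cat = 0L, age_first_birth_cat = 0L,
                 n_biopsies_cat = 0L, atypical_hyperplasia = "no",
                 n_affected_first_degree_cat = 0L)
}

# A valid three-generation toy family.
toy_family <- function(affected_mother = TRUE, test_cns = 0L) {
  tibble::tibble(
    family_id = "toy",
    member_id = c("1", "f", "m", "s1", "k1"),
    father_id = c("f", NA, NA, "f", NA),
    mother_id = c("m", NA, NA, "m", "1"),
    sex = c("F", "M", "F", "F", "F"),
    is_counselee = c(1L, 0L, 0L, 0L, 0L),
    age_baseline = c(30L, 40L, 38L, 27L, 12L),
    deceased = 0L,
    bc_affected = c(0L, 0L, if (affected_mother) 1L else 0L, 0L, NA),
    bc_onset_age = c(NA, NA, if (affected_mother) 33L else NA, NA, NA),
    oc_affected = c(0L, NA, 0L, 0L, NA),
    oc_onset_age = NA_integer_,
    test_brca1 = c(test_cns, 0L, 0L, 0L, 0L),
    test_brca2 = 0L
  )
}

# Random valid pedigree with at most `max_members` members (counselee kept),
# random phenotypes consistent with the invariants. Uses the ambient RNG.
random_pedigree <- function(max_members = 6, fid = "rp", a_max = 40,
                            p_test = 0) {
  rows <- list(list(id = "1", fa = NA, mo = NA, sex = "F", cns = 1L, age = sample(25:39, 1)))
  budget <- max_members - 1L
  age_of <- function(id) rows[[which(vapply(rows, function(r) r$id, "") == id)]]$age
  add <- function(id, fa, mo, sex, age) {
    rows[[length(rows) + 1L]] <<- list(id = id, fa = fa, mo = mo, sex = sex,
                                       cns = 0L, age = max(1L, min(age, a_max)))
    budget <<- budget - 1L
  }
  has_parents <- FALSE
  if (budget >= 2 && stats::runif(1) < 0.75) {
    a0 <- age_of("1")
    add("f", NA, NA, "M", a0 + sample(13:27, 1))
    add("m", NA, NA, "F", a0 + sample(13:27, 1))
    rows[[1]]$fa <- "f"; rows[[1]]$mo <- "m"
    has_parents <- TRUE
  }
  if (has_parents && budget >= 2 && stats::runif(1) < 0.4) {
    add("mgf", NA, NA, "M", age_of("m") + sample(13:20, 1))
    add("mgm", NA, NA, "F", age_of("m") + sample(13:20, 1))
    mi <- which(vapply(rows, function(r) r$id, "") == "m")
    rows[[mi]]$fa <- "mgf"; rows[[mi]]$mo <- "mgm"
    if (budget >= 1 && stats::runif(1) < 0.5) {
      add("ma1", "mgf", "mgm", sample(c("F", "M"), 1), age_of("m") - sample(-3:3, 1))
    }
  }
  while (budget > 0 && stats::runif(1) < 0.5) {
    k <- sum(vapply(rows, function(r) grepl("^s", r$id), TRUE))
    if (has_parents && stats::runif(1) < 0.6) {
      add(paste0("s", k + 1), "f", "m", sample(c("F", "M"), 1),
          age_of("1") + sample(-5:5, 1))
    } else {
      kk <- sum(vapply(rows, function(r) grepl("^k", r$id), TRUE))
      ka <- age_of("1") - sample(13:20, 1)
      if (ka < 1) break
      add(paste0("k", kk + 1), NA, "1", sample(c("F", "M"), 1), ka)
    }
  }
  df <- purrr::map_dfr(rows, function(r) {
    age <- r$age
    bc <- if (r$cns == 1L) 0L else if (r$sex == "M") {
      sample(c(0L, NA), 1, prob = c(.8, .2))
    } else sample(c(0L, 1L, NA), 1, prob = c(.6, .25, .15))
    oc <- if (r$sex == "F") sample(c(0L, 1L, NA), 1, prob = c(.75, .1, .15)) else NA
    t1 <- if (stats::runif(1) < p_test) sample(1:2, 1) else 0L
    tibble::tibble(
      family_id = fid, member_id = r$id, father_id = r$fa, mother_id = r$mo,
      sex = r$sex, is_counselee = r$cns, age_baseline = as.integer(age),
      deceased = ifelse(r$cns == 1L, 0L, stats::rbinom(1, 1, 0.2)),
      bc_affected = bc,
      bc_onset_age = if (isTRUE(bc == 1L)) sample(seq_len(age), 1) else NA_integer_,
      oc_affected = if (r$sex == "F") oc else NA_integer_,
      oc_onset_age = if (isTRUE(oc == 1L)) sample(seq_len(age), 1) else NA_integer_,
      test_brca1 = as.integer(t1), test_brca2 = 0L
    )
  })
  df
}

# Kinship-coefficient oracle: degree from 2 * kinship = (1/2)^degree.
kinship_degree_oracle <- function(fam) {
  ids <- fam$member_id
  fa <- match(fam$father_id, ids)
  mo <- match(fam$mother_id, ids)
  n <- nrow(fam)
  # generation depth to order recursion
  depth <- rep(0L, n)
  repeat {
    nd <- pmax(ifelse(is.na(fa), 0L, depth[fa] + 1L),
               ifelse(is.na(mo), 0L, depth[mo] + 1L))
    if (all(nd == depth)) break
    depth <- nd
  }
  phi <- matrix(NA_real_, n, n)
  ord <- order(depth)
  for (i in ord) {
    for (j in ord[seq_len(match(i, ord))]) {
      if (i == j) {
        pp <- if (!is.na(fa[i]) && !is.na(mo[i])) phi[fa[i], mo[i]] else 0
        phi[i, i] <- 0.5 * (1 + pp)
      } else {
        # i is at least as deep as j by ordering of the outer loop? ensure:
        a <- i; b <- j
        if (depth[a] < depth[b]) { a <- j; b <- i }
        v <- 0.5 * ((if (is.na(fa[a])) 0 else phi[min(fa[a], b), max(fa[a], b)]) +
                    (if (is.na(mo[a])) 0 else phi[min(mo[a], b), max(mo[a], b)]))
        phi[min(a, b), max(a, b)] <- v
        phi[max(a, b), min(a, b)] <- v
      }
    }
  }
  cz <- which(fam$is_counselee == 1L)
  vapply(seq_len(n), function(i) {
    if (i == cz) return(0L)
    k <- 2 * phi[min(i, cz), max(i, cz)]
    if (k <= 0) return(NA_integer_)
    as.integer(round(-log2(k)))
  }, integer(1))
}
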
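# Gail-style relative hazard and absolute risk projection.

#' Default relative-hazard coefficient set
#'
#' The published White-population log relative-hazard coefficients of the
#' Gail model structure: main effects for age at menarche (coded 0/1/2),
#' number of biopsies (0/1/2), age at first live birth (0/1/2/3) and number
#' of affected first-degree relatives (0/1/2), an (age band x biopsies)
#' interaction, an (age at first birth x affected relatives) interaction,
#' and atypical-hyperplasia multipliers applied when at least one biopsy
#' was taken. Values are configuration, not code: supply your own set for
#' other populations.
#'
#' @return A named list of coefficients.
#' @export
default_bcrat_coefficients <- function() {
  list(
    menarche = 0.09944,
    biopsies = 0.52926,
    first_birth = 0.21863,
    relatives = 0.95830,
    age_band2_x_biopsies = -0.28804,
    first_birth_x_relatives = -0.28812,
    ah_multiplier = c(no = 0.93, yes = 1.82, unknown = 1.0)
  )
}

#' Parameters of the relative-hazard absolute-risk model
#'
#' @param coefficients Named list as in [default_bcrat_coefficients()].
#' @param hazards Tibble with columns `age`, `h1` (baseline composite annual
#'   breast-cancer hazard), `h2` (annual competing mortality) and `f_cal`
#'   (attributable-risk calibration factor; 1 leaves the baseline hazard
#'   unscaled). Defaults to a synthetic baseline equal to the default
#'   non-carrier breast penetrance hazard with `f_cal = 1`.
#' @param age_bands Interior band edges for the age-interaction terms
#'   (default 50: bands `<50` and `>=50`).
#' @param min_age Minimum eligible baseline age (default 20).
#' @return An object of class `bcrat_params`.
#' @export
bcrat_params <- function(coefficients = default_bcrat_coefficients(),
                         hazards = default_bcrat_hazards(),
                         age_bands = 50,
                         min_age = 20) {
  stopifnot(all(c("menarche", "biopsies", "first_birth", "relatives",
                  "age_band2_x_biopsies", "first_birth_x_relatives",
                  "ah_multiplier") %in% names(coefficients)))
  stopifnot(all(c("age", "h1", "h2", "f_cal") %in% names(hazards)))
  assert_prob(hazards$h1, "h1"); assert_prob(hazards$h2, "h2")
  if (any(hazards$f_cal < 0)) {
    abort_combrisk("f_cal must be nonnegative", "combrisk_domain_error")
  }
  a_max <- max(hazards$age)
  hz <- hazards[order(hazards$age), ]
  if (!identical(as.integer(hz$age), seq_len(a_max))) {
    abort_combrisk("hazard table ages must be 1..a_max", "combrisk_schema_error")
  }
  structure(list(coefficients = coefficients,
                 h1 = hz$h1, h2 = hz$h2, f_cal = hz$f_cal,
                 age_bands = sort(age_bands), min_age = min_age,
                 a_max = a_max),
            class = "bcrat_params")
}

#' Default synthetic baseline hazard table for the relative-hazard model
#'
#' A synthetic SEER-like composite baseline hazard (its own Weibull-shaped
#' curve, deliberately distinct from the Mendelian model's non-carrier
#' penetrance table, as the two models draw their baselines from different
#' sources) and the default female competing mortality. The
#' attributable-risk calibration factor `F_cal` defaults to the published
#' White-population `1 - AR` values of the Gail model (0.5788 below age 50,
#' 0.4761 at 50 and above), which scale the covariate relative hazards to
#' be compatible with a population-average baseline hazard.
#'
#' @param a_max Maximum age.
#' @return A tibble with columns `age`, `h1`, `h2`, `f_cal`.
#' @export
default_bcrat_hazards <- function(a_max = 94) {
  mort <- default_mortality(a_max)
  ages <- seq_len(a_max)
  f1 <- weibull_annual(a_max, 4.05, 120, 1)
  F1 <- cumsum(f1)
  h1 <- pmin(f1 / c(1, 1 - F1[-a_max]), 1)
  tibble::tibble(
    age = ages,
    h1 = h1,
    h2 = mort$hazard[mort$sex == "female"],
    f_cal = ifelse(ages < 50, 0.5788413, 0.4761066)
  )
}

check_covariates <- function(cov) {
  if (!all(c("age_menarche_cat", "age_first_birth_cat", "n_biopsies_cat",
             "atypical_hyperplasia", "n_affected_first_degree_cat") %in% names(cov))) {
    abort_combrisk("covariate table must have columns age_menarche_cat, age_first_birth_cat, n_biopsies_cat, atypical_hyperplasia, n_affected_first_degree_cat",
                   "combrisk_schema_error")
  }
  ok <- all(cov$age_menarche_cat %in% 0:2) &&
    all(cov$age_first_birth_cat %in% 0:3) &&
    all(cov$n_biopsies_cat %in% 0:2) &&
    all(cov$atypical_hyperplasia %in% c("no", "yes", "unknown")) &&
    all(cov$n_affected_first_degree_cat %in% 0:2)
  if (!ok) abort_combrisk("unknown covariate category code", "combrisk_coding_error")
  invisible(cov)
}

#' Covariate relative-hazard profile
#'
#' Evaluates the multiplicative relative hazard `RR(a)` of each covariate
#' row as a step function of age: the exponentiated sum of the main-effect
#' and age-band interaction terms, times the atypical-hyperplasia
#' multiplier (applied only when at least one biopsy was taken; the
#' `unknown` category maps to the neutral multiplier 1).
#'
#' @param cov Covariate tibble (see [read_covariates()]; must also contain
#'   `n_affected_first_degree_cat`). An optional `family_id` column is
#'   carried through.
#' @param params [bcrat_params()].
#' @return A tibble with one row per covariate row and one `rr_band<k>`
#'   column per age band (bands are `params$age_bands`); plus a `bands`
#'   attribute. With default bands the columns are `rr_band1` (`age < 50`)
#'   and `rr_band2` (`age >= 50`).
#' @export
relative_hazard <- function(cov, params) {
  check_covariates(cov)
  cf <- params$coefficients
  main <- cf$menarche * cov$age_menarche_cat +
    cf$biopsies * cov$n_biopsies_cat +
    cf$first_birth * cov$age_first_birth_cat +
    cf$relatives * cov$n_affected_first_degree_cat +
    cf$first_birth_x_relatives * cov$age_first_birth_cat * cov$n_affected_first_degree_cat
  ah <- ifelse(cov$n_biopsies_cat > 0,
               cf$ah_multiplier[cov$atypical_hyperplasia], 1)
  n_bands <- length(params$age_bands) + 1L
  out <- tibble::tibble(.rows = nrow(cov))
  if ("family_id" %in% names(cov)) out$family_id <- cov$family_id
  for (b in seq_len(n_bands)) {
    inter <- if (b >= 2) cf$age_band2_x_biopsies * cov$n_biopsies_cat else 0
    out[[paste0("rr_band", b)]] <- exp(main + inter) * ah
  }
  attr(out, "bands") <- params$age_bands
  out
}

# RR at attained ages: rows of `rr` (profile tibble), vector of ages.
rr_at_age <- function(rr, ages) {
  bands <- attr(rr, "bands")
  b <- findInterval(ages, bands) + 1L
  cols <- as.matrix(rr[paste0("rr_band", seq_len(length(bands) + 1L))])
  cols[cbind(seq_len(nrow(cols)), b)]
}

# Full n x a_max matrix of RR(a) for each profile row.
rr_matrix <- function(rr, a_max) {
  bands <- attr(rr, "bands")
  b <- findInterval(seq_len(a_max), bands) + 1L
  cols <- as.matrix(rr[paste0("rr_band", seq_len(length(bands) + 1L))])
  cols[, b, drop = FALSE]
}

#' Absolute risk under the relative-hazard model
#'
#' Discrete competing-risk projection: the baseline composite breast-cancer
#' hazard `h1(a)`, scaled by the attributable-risk calibration factor
#' `F_cal(a)` and the covariate relative hazard `RR(a)`, accumulated
#' against competing mortality `h2(a)` over `tau` years from `age`.
#'
#' @param cov Covariate tibble (one row per counselee).
#' @param age Baseline age(s), recycled against rows of `cov`; all must be
#'   at least `params$min_age` (the model's eligibility rule).
#' @param tau Projection horizon in years.
#' @param params [bcrat_params()].
#' @return A tibble with `family_id` (if present), `tau` and `risk`.
#' @export
bcrat_absolute_risk <- function(cov, age, tau, params) {
  if (any(age < params$min_age)) {
    abort_combrisk(sprintf("baseline age below the model's eligibility minimum (%d)",
                           params$min_age), "combrisk_eligibility_error")
  }
  if (any(age + tau > params$a_max)) {
    abort_combrisk("age + tau outside the hazard table", "combrisk_range_error")
  }
  rr <- relative_hazard(cov, params)
  n <- max(nrow(cov), length(age))
  age <- rep_len(age, n)
  rrm <- rr_matrix(rr, params$a_max)
  h <- rrm * matrix(params$h1 * params$f_cal, nrow(rrm), params$a_max, byrow = TRUE)
  h <- pmin(h, 1)
  risk <- crude_risk_chain(age, tau, h, params$h2)
  out <- tibble::tibble(tau = tau, risk = risk)
  if ("family_id" %in% names(cov)) out <- dplyr::bind_cols(
    tibble::tibble(family_id = cov$family_id), out)
  out
}
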
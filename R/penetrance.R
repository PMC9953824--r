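#' Penetrance tables
#'
#' A penetrance table stores, for each cancer (breast, ovarian), sex, and
#' carrier class (`none`, `brca1`, `brca2`, `both`), the annual probability
#' `f(a)` of first diagnosis at age `a` for `a = 1, ..., a_max`. The
#' cumulative penetrance `F(a)` is the running sum of `f`, and the
#' conditional annual hazard is `h(a) = f(a) / (1 - F(a - 1))`. Ages are
#' whole years; "age a" phenotypes mean status as of the end of year `a`.
#'
#' @param df A data frame with columns `age`, `cancer` (`"breast"` or
#'   `"ovarian"`), `sex` (`"female"` or `"male"`), and annual onset
#'   probabilities `class_none`, `class_brca1`, `class_brca2`, `class_both`.
#'   Ovarian rows are required for females only.
#' @return An object of class `penetrance_table`.
#' @export
penetrance_table <- function(df) {
  req <- c("age", "cancer", "sex", paste0("class_", CARRIER_CLASSES))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort_combrisk(paste0("penetrance table is missing columns: ",
                          paste(missing_cols, collapse = ", ")),
                   "combrisk_schema_error")
  }
  a_max <- max(df$age)
  combos <- list(
    breast_female  = c("breast", "female"),
    breast_male    = c("breast", "male"),
    ovarian_female = c("ovarian", "female")
  )
  f <- lapply(combos, function(cs) {
    sub <- df[df$cancer == cs[1] & df$sex == cs[2], , drop = FALSE]
    m <- matrix(0, nrow = a_max, ncol = 4,
                dimnames = list(NULL, CARRIER_CLASSES))
    if (nrow(sub) > 0) {
      sub <- sub[order(sub$age), ]
      if (!identical(as.integer(sub$age), seq_len(a_max))) {
        abort_combrisk(sprintf("penetrance ages for %s/%s must be 1..%d",
                               cs[1], cs[2], a_max), "combrisk_schema_error")
      }
      m[, "none"]  <- sub$class_none
      m[, "brca1"] <- sub$class_brca1
      m[, "brca2"] <- sub$class_brca2
      m[, "both"]  <- sub$class_both
    }
    if (any(m < 0)) {
      abort_combrisk("annual penetrances must be nonnegative", "combrisk_domain_error")
    }
    if (any(colSums(m) > 1 + 1e-12)) {
      abort_combrisk("cumulative penetrance F(a_max) exceeds 1", "combrisk_domain_error")
    }
    m
  })
  Fm <- lapply(f, function(m) apply(m, 2, cumsum))
  h <- mapply(function(fm, Fm1) {
    surv_prev <- rbind(rep(1, 4), 1 - Fm1[-nrow(Fm1), , drop = FALSE])
    hz <- ifelse(surv_prev > 0, fm / surv_prev, 0)
    pmin(hz, 1)
  }, f, Fm, SIMPLIFY = FALSE)
  structure(list(a_max = a_max, f = f, F = Fm, h = h),
            class = "penetrance_table")
}

#' @export
print.penetrance_table <- function(x, ...) {
  cat("<penetrance_table> a_max =", x$a_max, "\n")
  cat("  lifetime breast (female):",
      paste(sprintf("%s=%.3f", CARRIER_CLASSES, x$F$breast_female[x$a_max, ]),
            collapse = " "), "\n")
  invisible(x)
}

#' Convert a penetrance table to a tidy tibble
#'
#' @param x A `penetrance_table`.
#' @param ... Unused.
#' @return A tibble in the on-disk dialect accepted by [penetrance_table()].
#' @exportS3Method tibble::as_tibble
as_tibble.penetrance_table <- function(x, ...) {
  combos <- list(
    breast_female  = c("breast", "female"),
    breast_male    = c("breast", "male"),
    ovarian_female = c("ovarian", "female")
  )
  purrr::map_dfr(names(combos), function(nm) {
    m <- x$f[[nm]]
    tibble::tibble(
      age = seq_len(x$a_max),
      cancer = combos[[nm]][1], sex = combos[[nm]][2],
      class_none = m[, "none"], class_brca1 = m[, "brca1"],
      class_brca2 = m[, "brca2"], class_both = m[, "both"]
    )
  })
}

# Discrete annual onset probabilities from a Weibull-shaped cumulative curve.
weibull_annual <- function(a_max, shape, scale, cap) {
  ages <- seq_len(a_max)
  Fc <- cap * (1 - exp(-(ages / scale)^shape))
  c(Fc[1], diff(Fc))
}

#' Default synthetic penetrance fixture
#'
#' Smooth Weibull-shaped annual penetrance curves for the four carrier
#' classes. These are synthetic stand-ins with realistic magnitudes
#' (e.g. female breast cancer cumulative penetrance by age 70 of roughly 0.12
#' for non-carriers, 0.57 for BRCA1 carriers and 0.45 for BRCA2 carriers),
#' not literature estimates; users supply literature tables via
#' [penetrance_table()] for real analyses. The `both` class is the
#' elementwise maximum of the two single-gene classes.
#'
#' @param a_max Maximum age in the table (default 94).
#' @return A `penetrance_table`.
#' @export
default_penetrance <- function(a_max = 94) {
  bf <- cbind(
    none  = weibull_annual(a_max, 4.2, 115, 1),
    brca1 = weibull_annual(a_max, 2.5, 75, 1),
    brca2 = weibull_annual(a_max, 2.8, 85, 1)
  )
  bf <- cbind(bf, both = pmax(bf[, "brca1"], bf[, "brca2"]))
  bm <- cbind(
    none  = weibull_annual(a_max, 5, 500, 1),
    brca1 = weibull_annual(a_max, 4, 300, 1),
    brca2 = weibull_annual(a_max, 3.5, 180, 1)
  )
  bm <- cbind(bm, both = pmax(bm[, "brca1"], bm[, "brca2"]))
  ov <- cbind(
    none  = weibull_annual(a_max, 5, 220, 1),
    brca1 = weibull_annual(a_max, 3, 110, 1),
    brca2 = weibull_annual(a_max, 3, 150, 1)
  )
  ov <- cbind(ov, both = pmax(ov[, "brca1"], ov[, "brca2"]))
  build <- function(m, cancer, sex) {
    tibble::tibble(age = seq_len(a_max), cancer = cancer, sex = sex,
                   class_none = m[, "none"], class_brca1 = m[, "brca1"],
                   class_brca2 = m[, "brca2"], class_both = m[, "both"])
  }
  penetrance_table(dplyr::bind_rows(
    build(bf, "breast", "female"),
    build(bm, "breast", "male"),
    build(ov, "ovarian", "female")
  ))
}

#' Default synthetic competing-mortality table
#'
#' Gompertz-like annual hazards of death from causes other than breast
#' cancer, by age and sex. Synthetic fixture built in code.
#'
#' @param a_max Maximum age (default 94).
#' @return A tibble with columns `age`, `sex`, `hazard`.
#' @export
default_mortality <- function(a_max = 94) {
  ages <- seq_len(a_max)
  hf <- pmin(5e-5 * exp(0.105 * pmax(ages - 20, 0)) + 2e-4, 0.5)
  hm <- pmin(8e-5 * exp(0.103 * pmax(ages - 20, 0)) + 3e-4, 0.5)
  dplyr::bind_rows(
    tibble::tibble(age = ages, sex = "female", hazard = hf),
    tibble::tibble(age = ages, sex = "male", hazard = hm)
  )
}

#' Parameters of the Mendelian two-gene model
#'
#' Bundles allele frequencies, penetrance tables, competing mortality and
#' genetic-test accuracy into the parameter object consumed by
#' [carrier_posteriors()], [brcapro_risk()] and the simulator.
#'
#' @param allele_freq_brca1,allele_freq_brca2 Deleterious allele frequencies
#'   (each in (0, 0.5); 0 is accepted and means the gene is absent from the
#'   population). Defaults are Ashkenazi-like higher-risk values.
#' @param penetrance A [penetrance_table()].
#' @param mortality Tibble with columns `age`, `sex`, `hazard` (annual
#'   other-cause mortality).
#' @param test_sensitivity,test_specificity Accuracy of BRCA1/2 germline
#'   testing (default 1, i.e. perfect tests).
#' @return An object of class `mendelian_params`.
#' @export
mendelian_params <- function(allele_freq_brca1 = 0.013,
                             allele_freq_brca2 = 0.009,
                             penetrance = default_penetrance(),
                             mortality = default_mortality(penetrance$a_max),
                             test_sensitivity = 1,
                             test_specificity = 1) {
  for (q in c(allele_freq_brca1, allele_freq_brca2)) {
    if (!is.finite(q) || q < 0 || q >= 0.5) {
      abort_combrisk("allele frequencies must lie in [0, 0.5)", "combrisk_domain_error")
    }
  }
  stopifnot(inherits(penetrance, "penetrance_table"))
  assert_prob(mortality$hazard, "mortality$hazard")
  assert_prob(test_sensitivity, "test_sensitivity")
  assert_prob(test_specificity, "test_specificity")
  a_max <- penetrance$a_max
  mort <- matrix(0, nrow = a_max, ncol = 2, dimnames = list(NULL, c("female", "male")))
  for (s in c("female", "male")) {
    sub <- mortality[mortality$sex == s, ]
    mort[sub$age, s] <- sub$hazard
  }
  structure(list(
    allele_freq_brca1 = allele_freq_brca1,
    allele_freq_brca2 = allele_freq_brca2,
    penetrance = penetrance,
    mortality = mort,
    test_sensitivity = test_sensitivity,
    test_specificity = test_specificity,
    a_max = a_max
  ), class = "mendelian_params")
}

#' @export
print.mendelian_params <- function(x, ...) {
  cat("<mendelian_params> q1 =", x$allele_freq_brca1,
      " q2 =", x$allele_freq_brca2, " a_max =", x$a_max, "\n")
  invisible(x)
}

#' Genotype state for the two-gene model
#'
#' @param copies_brca1,copies_brca2 Number of deleterious alleles (0, 1, 2).
#' @return A list with the copy numbers and the derived `carrier_class`
#'   (`"none"`, `"brca1"`, `"brca2"`, or `"both"`).
#' @export
genotype_state <- function(copies_brca1, copies_brca2) {
  stopifnot(copies_brca1 %in% 0:2, copies_brca2 %in% 0:2)
  cls <- carrier_class_of(copies_brca1, copies_brca2)
  list(copies_brca1 = copies_brca1, copies_brca2 = copies_brca2,
       carrier_class = cls)
}

carrier_class_of <- function(c1, c2) {
  dplyr::case_when(
    c1 > 0 & c2 > 0 ~ "both",
    c1 > 0 ~ "brca1",
    c2 > 0 ~ "brca2",
    TRUE ~ "none"
  )
}
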
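test_that("unit relative hazard leaves the penetrance unchanged", {
  mp <- mendelian_params()
  pen2 <- modify_noncarrier_hazard(mp, rep(1, mp$a_max))
  expect_equal(pen2$f$breast_female[, "none"], mp$penetrance$f$breast_female[, "none"],
               tolerance = 1e-14)
  expect_identical(pen2$f$breast_female[, "brca1"], mp$penetrance$f$breast_female[, "brca1"])
})

test_that("hazard scaling follows the closed form and the recursion", {
  h <- 0.01
  mp <- mendelian_params(penetrance = const_hazard_penetrance(
    h = c(none = h, brca1 = 0.05, brca2 = 0.03, both = 0.05)),
    mortality = zero_mortality(40))
  pen2 <- modify_noncarrier_hazard(mp, rep(2, 40))
  ages <- 1:40
  expect_equal(pen2$F$breast_female[, "none"], 1 - (1 - 2 * h)^ages,
               tolerance = 1e-12)
  # carrier columns bit-identical
  expect_identical(pen2$f$breast_female[, "brca1"],
                   mp$penetrance$f$breast_female[, "brca1"])

  # age-varying profile against hazard-by-hazard recomputation
  rrv <- seq(0.8, 2.5, length.out = 40)
  pen3 <- modify_noncarrier_hazard(mp, rrv)
  h0 <- mp$penetrance$h$breast_female[, "none"]
  hn <- pmin(h0 * rrv, 1)
  S <- cumprod(1 - hn)
  expect_equal(pen3$h$breast_female[, "none"], hn, tolerance = 1e-12)
  expect_equal(pen3$f$breast_female[, "none"], hn * c(1, S[-40]), tolerance = 1e-12)

  expect_warning(modify_noncarrier_hazard(mp, rep(200, 40)),
                 class = "combrisk_clip_warning")
})

test_that("combined risk reduces to the family-history risk when RR is one", {
  mp <- tiny_mendelian_params()
  bp <- neutral_bcrat_params(a_max = 40)
  ped <- toy_family()
  cov <- reference_covariates(family_id = "toy")
  expect_equal(bbm_risk(ped, cov, mp, bp, 5)$risk,
               brcapro_risk(ped, mp, 5)$risk, tolerance = 1e-14)
})

test_that("combined risk is monotone in the relative hazard and carrier-invariant", {
  mp <- tiny_mendelian_params()
  bp <- bcrat_params(hazards = dplyr::mutate(default_bcrat_hazards(94), f_cal = 1))
  ped <- toy_family()
  cov_lo <- reference_covariates(family_id = "toy")
  cov_hi <- dplyr::mutate(cov_lo, n_biopsies_cat = 2L)
  r_lo <- bbm_risk(ped, cov_lo, mp, bp, 5)$risk
  r_hi <- bbm_risk(ped, cov_hi, mp, bp, 5)$risk
  expect_gt(r_hi, r_lo)

  # a perfect positive test makes the result independent of the covariates
  ped_t <- toy_family(test_cns = 1L)
  r1 <- bbm_risk(ped_t, cov_lo, mp, bp, 5)$risk
  r2 <- bbm_risk(ped_t, cov_hi, mp, bp, 5)$risk
  expect_equal(r1, r2, tolerance = 1e-14)
})

test_that("combined risk equals the two-step posterior/modified-penetrance oracle", {
  mp <- tiny_mendelian_params(q1 = 0.06, q2 = 0.03)
  bp <- bcrat_params(hazards = dplyr::mutate(default_bcrat_hazards(94), f_cal = 1))
  ped <- toy_family()
  cov <- dplyr::mutate(reference_covariates(family_id = "toy"),
                       n_biopsies_cat = 1L, age_menarche_cat = 2L,
                       n_affected_first_degree_cat = 1L)
  post <- carrier_posteriors(ped, mp)
  rr <- relative_hazard(cov, bp)
  rr_vec <- combrisk:::rr_matrix(rr, mp$a_max)[1, ]
  pen_mod <- modify_noncarrier_hazard(mp, rr_vec)
  a0 <- ped$age_baseline[ped$is_counselee == 1L]
  want <- post$p_none * genotype_future_risk(a0, 5, "none", mp, penetrance = pen_mod) +
    post$p_brca1 * genotype_future_risk(a0, 5, "brca1", mp) +
    post$p_brca2 * genotype_future_risk(a0, 5, "brca2", mp) +
    post$p_both * genotype_future_risk(a0, 5, "both", mp)
  expect_equal(bbm_risk(ped, cov, mp, bp, 5)$risk, want, tolerance = 1e-12)
})

sim_logit_rows <- function(n, beta, seed) {
  set.seed(seed)
  p1 <- stats::runif(n, 0.001, 0.25)
  p2 <- pmin(pmax(p1 * exp(stats::rnorm(n, 0, 0.8)), 1e-4), 0.4)
  x1 <- sqrt(p1); x2 <- sqrt(p2)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + beta[4] * x1 * x2
  tibble::tibble(p_brcapro = p1, p_bcrat = p2,
                 outcome = stats::rbinom(n, 1, stats::plogis(eta)))
}

test_that("stacked logistic fitting recovers coefficients and respects weights", {
  beta <- c(-3.5, 4, 3, -2)
  d <- sim_logit_rows(20000, beta, seed = 11)
  fit <- fit_stacked_logistic(d)
  td <- tidy(fit)
  expect_true(all(abs(td$estimate - beta) <= 3 * td$std.error))

  # constant positive weights leave the fit unchanged
  fit_w <- fit_stacked_logistic(d[1:2000, ], weights = rep(2.5, 2000))
  fit_u <- fit_stacked_logistic(d[1:2000, ])
  expect_equal(fit_w$coefficients, fit_u$coefficients, tolerance = 1e-8)

  # collinear base predictions: warning surfaced, fit still returned
  d2 <- d[1:500, ]; d2$p_bcrat <- d2$p_brcapro
  expect_warning(fit2 <- fit_stacked_logistic(d2),
                 class = "combrisk_collinearity_warning")
  expect_s3_class(fit2, "stacked_logistic")
  expect_true(all(is.finite(predict(fit2, d2))))

  d3 <- d[1:100, ]; d3$outcome <- 0L
  expect_error(fit_stacked_logistic(d3), class = "combrisk_degenerate_error")
})

test_that("unweighted stacked logistic predictions are calibrated in the large", {
  d <- sim_logit_rows(5000, c(-3, 3, 2, 0), seed = 12)
  fit <- fit_stacked_logistic(d)
  p <- predict(fit, d)
  expect_equal(sum(p), sum(d$outcome), tolerance = 1e-6)
})

test_that("stacked logistic prediction is the inverse-logit of the linear predictor", {
  m <- structure(list(coefficients = c(0, 0, 0, 0)), class = "stacked_logistic")
  expect_equal(predict_stacked_logistic(m, 0.1, 0.2), 0.5)
  m2 <- structure(list(coefficients = c(-1.3, 0, 0, 0)), class = "stacked_logistic")
  expect_equal(predict_stacked_logistic(m2, 0.5, 0.9), stats::plogis(-1.3))
  b <- c(-2, 1.5, 0.7, -0.4)
  m3 <- structure(list(coefficients = b), class = "stacked_logistic")
  expect_equal(predict_stacked_logistic(m3, 0.04, 0.09),
               stats::plogis(b[1] + b[2] * 0.2 + b[3] * 0.3 + b[4] * 0.06))
})

sim_surv_rows <- function(n, beta, seed, p_death = 0.1, admin = 5) {
  set.seed(seed)
  p1 <- stats::runif(n, 0.001, 0.25)
  p2 <- pmin(pmax(p1 * exp(stats::rnorm(n, 0, 0.8)), 1e-4), 0.4)
  x1 <- sqrt(p1); x2 <- sqrt(p2)
  lp <- beta[1] * x1 + beta[2] * x2 + beta[3] * x1 * x2
  t_bc <- stats::rexp(n, 0.04 * exp(lp))
  t_d <- if (p_death > 0) stats::rexp(n, 0.04 * p_death / (1 - p_death)) else rep(Inf, n)
  time <- pmin(t_bc, t_d, admin)
  cause <- ifelse(time == t_bc, "bc", ifelse(time == t_d, "death", "none"))
  tibble::tibble(p_brcapro = p1, p_bcrat = p2, time = time, cause = cause)
}

test_that("the subdistribution fit matches a cause-specific fit without competing events", {
  d <- sim_surv_rows(3000, c(2, 1, 0), seed = 21, p_death = 0)
  fit <- fit_stacked_finegray(d)
  x1 <- sqrt(d$p_brcapro); x2 <- sqrt(d$p_bcrat)
  cox <- survival::coxph(survival::Surv(d$time, d$cause == "bc") ~
                           x1 + x2 + I(x1 * x2), ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(stats::coef(cox)), tolerance = 1e-6)
})

test_that("the subdistribution fit recovers null coefficients with competing risks", {
  d <- sim_surv_rows(8000, c(0, 0, 0), seed = 22, p_death = 0.3)
  expect_gt(sum(d$cause == "death"), 0)
  fit <- fit_stacked_finegray(d)
  td <- tidy(fit)
  expect_true(all(abs(td$estimate) <= 3 * td$std.error))
})

test_that("subdistribution fitting validates its inputs", {
  d <- sim_surv_rows(500, c(1, 1, 0), seed = 23)
  d2 <- d; d2$p_bcrat <- d2$p_brcapro
  expect_warning(fit_stacked_finegray(d2), class = "combrisk_collinearity_warning")
  d3 <- d; d3$cause <- "none"
  expect_error(fit_stacked_finegray(d3), class = "combrisk_fit_error")
  d4 <- d; d4$time[1] <- 0
  expect_error(fit_stacked_finegray(d4), class = "combrisk_domain_error")
})

test_that("predicted cumulative incidence matches the survival-curve route", {
  d <- sim_surv_rows(4000, c(2, 1, -0.5), seed = 24, p_death = 0.2)
  fit <- fit_stacked_finegray(d)
  expect_equal(predict_cif(fit, 0.05, 0.1, 0), 0)
  # independent route: survfit on the weighted Cox model
  nd <- tibble::tibble(x1 = sqrt(0.05), x2 = sqrt(0.1), x3 = sqrt(0.05 * 0.1))
  sf <- survival::survfit(fit$fit, newdata = nd)
  for (tau in c(1, 3, 5)) {
    ours <- predict_cif(fit, 0.05, 0.1, tau)
    # survfit uses the exact exp(-H) transform on the same Breslow hazard
    idx <- max(which(sf$time <= tau))
    expect_equal(ours, 1 - sf$surv[idx], tolerance = 1e-8)
  }
  cifs <- vapply(1:5, function(tau) predict_cif(fit, 0.05, 0.1, tau), numeric(1))
  expect_true(all(diff(cifs) >= 0))
  expect_error(predict_cif(fit, 0.05, 0.1, 99), class = "combrisk_range_error")
})

test_that("ensembles serialise to YAML", {
  d <- sim_logit_rows(2000, c(-3, 2, 2, 0), seed = 31)
  fit <- fit_stacked_logistic(d)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ensemble(fit, path)
  doc <- yaml::read_yaml(path)
  expect_equal(doc$type, "stacked_logistic")
  expect_equal(unlist(doc$coefficients), fit$coefficients, tolerance = 1e-9)
})
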
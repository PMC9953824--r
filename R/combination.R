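# The two combination approaches: penetrance modification of the
# non-carrier hazard by the covariate relative hazard, and stacked
# ensembles (logistic and Fine-Gray) over transformed base-model
# predictions.

#' Modify the non-carrier breast-cancer hazard by a relative-hazard profile
#'
#' Scales the non-carrier female annual breast-cancer hazard `h0(a)` to
#' `min(1, h0(a) * F_cal(a) * RR(a))` under a discrete proportional-hazards
#' model and recomputes the non-carrier annual and cumulative penetrance
#' from the scaled hazard. Carrier-class columns are left bit-identical;
#' a warning is raised if any scaled hazard had to be clipped at 1.
#'
#' @param params [mendelian_params()].
#' @param rr A one-row relative-hazard profile from [relative_hazard()], or
#'   a numeric vector of length `a_max` giving `RR(a)` directly.
#' @param f_cal Optional attributable-risk calibration factors by age
#'   (length `a_max`); default 1 at every age.
#' @return A `penetrance_table` with the non-carrier female breast column
#'   replaced.
#' @export
modify_noncarrier_hazard <- function(params, rr, f_cal = NULL) {
  pen <- params$penetrance
  a_max <- pen$a_max
  if (is.data.frame(rr)) {
    if (nrow(rr) != 1) abort_combrisk("`rr` must be a single profile row",
                                      "combrisk_domain_error")
    rr_vec <- as.numeric(rr_matrix(rr, a_max))
  } else {
    rr_vec <- rep_len(as.numeric(rr), a_max)
  }
  f_cal <- f_cal %||% rep(1, a_max)
  h0 <- pen$h$breast_female[, "none"]
  h_new <- h0 * rr_vec * f_cal
  if (any(h_new > 1)) {
    rlang::warn("scaled non-carrier hazard clipped at 1 for some ages",
                class = "combrisk_clip_warning")
    h_new <- pmin(h_new, 1)
  }
  S <- cumprod(1 - h_new)
  f_new <- h_new * c(1, S[-a_max])
  pen2 <- pen
  pen2$h$breast_female[, "none"] <- h_new
  pen2$f$breast_female[, "none"] <- f_new
  pen2$F$breast_female[, "none"] <- cumsum(f_new)
  pen2
}

#' Penetrance-modification combined risk
#'
#' The combined model's future risk: the Mendelian carrier-class posterior
#' mixed with genotype-specific crude risks, where the non-carrier class
#' uses the hazard modified by the counselee's covariate relative hazard
#' (carrier classes are untouched, as the relative-hazard model is not
#' recommended for known mutation carriers).
#'
#' @param peds Validated pedigree tibble.
#' @param cov Covariate tibble with `family_id` and, optionally,
#'   `n_affected_first_degree_cat` (derived from the pedigree when absent).
#' @param mparams [mendelian_params()].
#' @param bparams [bcrat_params()] (supplies the relative-hazard
#'   coefficients and `F_cal`).
#' @param tau Projection horizon in years.
#' @param validate Revalidate pedigrees first.
#' @return A tibble with `family_id`, `tau`, `risk`.
#' @export
bbm_risk <- function(peds, cov, mparams, bparams, tau, validate = TRUE) {
  if (validate) peds <- validate_pedigrees(peds, a_max = mparams$a_max)
  cov <- derive_family_covariates(peds, cov)
  post <- carrier_posteriors(peds, mparams, validate = FALSE)
  cov <- cov[match(post$family_id, cov$family_id), ]
  cz <- peds[peds$is_counselee == 1L, ]
  cz <- cz[match(post$family_id, cz$family_id), ]
  rr <- relative_hazard(cov, bparams)
  risk <- bbm_risk_vec(cz$age_baseline, tau, post, rr, mparams, bparams)
  tibble::tibble(family_id = post$family_id, tau = tau, risk = risk)
}

# Vectorised mixture risk given posteriors and RR profiles.
bbm_risk_vec <- function(a0, tau, post, rr, mparams, bparams) {
  pen <- mparams$penetrance
  a_max <- pen$a_max
  h0 <- pen$h$breast_female[, "none"]
  f_cal <- rep(1, a_max)
  k <- min(a_max, bparams$a_max)
  f_cal[seq_len(k)] <- bparams$f_cal[seq_len(k)]
  h_mod <- rr_matrix(rr, a_max) *
    matrix(h0 * f_cal, nrow(rr), a_max, byrow = TRUE)
  h_mod <- pmin(h_mod, 1)
  h_d <- mparams$mortality[, "female"]
  risk_none <- crude_risk_chain(a0, tau, h_mod, h_d)
  carrier_risks <- vapply(c("brca1", "brca2", "both"), function(cl) {
    genotype_future_risk(a0, tau, cl, mparams)
  }, numeric(length(a0)))
  if (is.null(dim(carrier_risks))) carrier_risks <- matrix(carrier_risks, nrow = 1)
  post$p_none * risk_none +
    post$p_brca1 * carrier_risks[, 1] +
    post$p_brca2 * carrier_risks[, 2] +
    post$p_both * carrier_risks[, 3]
}

# Fill in pedigree-derived covariate fields.
derive_family_covariates <- function(peds, cov) {
  cov <- tibble::as_tibble(cov)
  if (!"n_affected_first_degree_cat" %in% names(cov)) {
    counts <- count_affected_first_degree(peds)
    cov <- dplyr::left_join(cov, counts, by = "family_id")
    cov$n_affected_first_degree_cat <- pmin(cov$n_affected_first_degree, 2L)
    cov$n_affected_first_degree <- NULL
  }
  cov
}

# ---- Stacked ensembles ------------------------------------------------------

stack_design <- function(p_brcapro, p_bcrat) {
  assert_prob(p_brcapro, "p_brcapro"); assert_prob(p_bcrat, "p_bcrat")
  x1 <- sqrt(p_brcapro); x2 <- sqrt(p_bcrat)
  tibble::tibble(x1 = x1, x2 = x2, x3 = x1 * x2)
}

warn_if_collinear <- function(x1, x2) {
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0 ||
      abs(stats::cor(x1, x2)) > 0.999) {
    rlang::warn("base-model predictions are (nearly) collinear; stacked coefficients may be unstable",
                class = "combrisk_collinearity_warning")
  }
}

#' Fit the stacked logistic ensemble
#'
#' Logistic regression of the tau-year binary outcome on the square-root
#' transformed base-model predictions and their product (the transform is
#' applied first, then the product is taken). Optional nonnegative row
#' weights (e.g. importance weights) enter as weighted maximum likelihood.
#'
#' @param data Data frame with columns `p_brcapro`, `p_bcrat` (tau-year
#'   probabilities in `[0,1]`) and `outcome` (0/1 event within tau years).
#' @param weights Optional nonnegative per-row weights.
#' @param tau The horizon the predictions refer to (metadata; default 5).
#' @return An object of class `stacked_logistic`.
#' @export
fit_stacked_logistic <- function(data, weights = NULL, tau = 5) {
  y <- data$outcome
  if (!all(y %in% c(0, 1))) abort_combrisk("outcome must be binary 0/1",
                                           "combrisk_domain_error")
  if (length(unique(y)) < 2) {
    abort_combrisk("outcome is constant: at least one event and one non-event required",
                   "combrisk_degenerate_error")
  }
  X <- stack_design(data$p_brcapro, data$p_bcrat)
  warn_if_collinear(X$x1, X$x2)
  df <- dplyr::bind_cols(X, tibble::tibble(.y = y))
  w <- weights %||% rep(1, nrow(df))
  if (any(w < 0)) abort_combrisk("weights must be nonnegative", "combrisk_domain_error")
  df$.w <- w
  fit <- withCallingHandlers(
    stats::glm(.y ~ x1 + x2 + x3, family = stats::binomial(), data = df,
               weights = .w),
    warning = function(w_) {
      if (grepl("non-integer #successes", conditionMessage(w_))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    abort_combrisk(paste0("stacked logistic fit did not converge (deviance ",
                          round(fit$deviance, 3), ", possible separation)"),
                   "combrisk_fit_error")
  }
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 tau = tau,
                 weighted = !is.null(weights),
                 n = nrow(df), n_events = sum(y)),
            class = "stacked_logistic")
}

#' Predict from a stacked logistic ensemble
#'
#' Inverse-logit of the linear predictor on the transformed base-model
#' predictions.
#'
#' @param object A `stacked_logistic` model.
#' @param p_brcapro,p_bcrat Base-model predictions in `[0,1]`.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_stacked_logistic <- function(object, p_brcapro, p_bcrat) {
  X <- stack_design(p_brcapro, p_bcrat)
  b <- object$coefficients
  b[is.na(b)] <- 0  # aliased terms under exact collinearity
  unname(stats::plogis(b[1] + b[2] * X$x1 + b[3] * X$x2 + b[4] * X$x3))
}

#' @export
predict.stacked_logistic <- function(object, newdata, ...) {
  predict_stacked_logistic(object, newdata$p_brcapro, newdata$p_bcrat)
}

#' Fit the stacked Fine-Gray ensemble
#'
#' Proportional subdistribution-hazards model for breast cancer with death
#' as a competing risk, using the square-root transformed base-model
#' predictions (computed at the fixed horizon `tau_star`) and their product
#' as covariates. Subjects failing from the competing cause remain in the
#' risk sets with censoring-distribution weights (the Fine-Gray
#' construction, via [survival::finegray()]); the baseline subdistribution
#' cumulative hazard is the Breslow estimator at covariate value zero.
#'
#' @param data Data frame with columns `p_brcapro`, `p_bcrat` (predictions
#'   at `tau_star`), `time` (positive follow-up years) and `cause` (one of
#'   `"none"` (censored), `"bc"`, `"death"`).
#' @param weights Optional nonnegative per-row case weights.
#' @param tau_star Horizon at which the covariate predictions were computed
#'   (metadata; default 5).
#' @return An object of class `stacked_finegray`.
#' @export
fit_stacked_finegray <- function(data, weights = NULL, tau_star = 5) {
  if (any(data$time <= 0)) abort_combrisk("times must be positive",
                                          "combrisk_domain_error")
  if (!all(data$cause %in% c("none", "bc", "death"))) {
    abort_combrisk("cause must be one of 'none', 'bc', 'death'",
                   "combrisk_coding_error")
  }
  if (sum(data$cause == "bc") == 0) {
    abort_combrisk("no breast-cancer events: cannot fit the subdistribution model",
                   "combrisk_fit_error")
  }
  X <- stack_design(data$p_brcapro, data$p_bcrat)
  warn_if_collinear(X$x1, X$x2)
  df <- dplyr::bind_cols(X, tibble::tibble(
    .time = data$time,
    .status = factor(data$cause, levels = c("none", "bc", "death"))
  ))
  df$.w <- weights %||% rep(1, nrow(df))
  fg <- survival::finegray(survival::Surv(.time, .status) ~ x1 + x2 + x3,
                           data = df, weights = .w, etype = "bc")
  fit <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ x1 + x2 + x3,
    data = fg, weights = fgwt, ties = "breslow")
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 basehaz = tibble::tibble(time = bh$time, hazard = bh$hazard),
                 tau_star = tau_star,
                 max_time = max(data$time),
                 weighted = !is.null(weights),
                 n = nrow(df), n_events = sum(data$cause == "bc")),
            class = "stacked_finegray")
}

#' Predicted cumulative incidence from the stacked Fine-Gray ensemble
#'
#' `1 - exp(-Lambda0(tau) * exp(linear predictor))`, nondecreasing in
#' `tau`.
#'
#' @param object A `stacked_finegray` model.
#' @param p_brcapro,p_bcrat Base-model predictions (at `tau_star`).
#' @param tau Horizon; must not exceed the largest observed training time.
#' @return Cumulative incidence probabilities.
#' @export
predict_cif <- function(object, p_brcapro, p_bcrat, tau) {
  if (tau > object$max_time) {
    abort_combrisk("tau beyond the observed training horizon", "combrisk_range_error")
  }
  if (tau <= 0) return(rep(0, length(p_brcapro)))
  X <- stack_design(p_brcapro, p_bcrat)
  b <- object$coefficients
  b[is.na(b)] <- 0  # aliased terms under exact collinearity
  lp <- b[1] * X$x1 + b[2] * X$x2 + b[3] * X$x3
  bh <- object$basehaz
  idx <- findInterval(tau, bh$time)
  L0 <- if (idx == 0) 0 else bh$hazard[idx]
  unname(1 - exp(-L0 * exp(lp)))
}

#' @export
predict.stacked_finegray <- function(object, newdata, tau = object$tau_star, ...) {
  predict_cif(object, newdata$p_brcapro, newdata$p_bcrat, tau)
}

#' Serialise a fitted ensemble to YAML
#'
#' Writes coefficient names and values, the transform specification, the
#' horizon, and (for the Fine-Gray ensemble) the baseline subdistribution
#' hazard steps.
#'
#' @param object A `stacked_logistic` or `stacked_finegray` model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(object, path) {
  doc <- list(
    type = class(object)[1],
    transform = "sqrt, then product interaction",
    coefficients = as.list(object$coefficients)
  )
  if (inherits(object, "stacked_logistic")) {
    doc$tau <- object$tau
  } else {
    doc$tau_star <- object$tau_star
    doc$basehaz <- list(time = object$basehaz$time,
                        hazard = object$basehaz$hazard)
  }
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
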
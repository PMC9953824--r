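# Batch predictions for a cohort of counselees: the Mendelian model, the
# relative-hazard model, and the penetrance-modification combination, all
# at the same horizon.

#' Base-model and combined predictions for every counselee
#'
#' Computes, for each family, the tau-year breast-cancer risk from the
#' Mendelian family-history model (`p_brcapro`), the relative-hazard model
#' (`p_bcrat`), and the penetrance-modification combination (`p_bbm`).
#' The number of affected first-degree relatives is derived from the
#' pedigree when the covariate table does not carry it.
#'
#' @param peds Pedigree tibble (eligible families).
#' @param cov Covariate tibble with `family_id`.
#' @param mparams [mendelian_params()].
#' @param bparams [bcrat_params()].
#' @param tau Horizon in years (default 5).
#' @param validate Validate pedigrees first (default TRUE; turn off for
#'   trusted simulator output).
#' @return A tibble with `family_id`, `age_baseline`, `p_brcapro`,
#'   `p_bcrat`, `p_bbm`, plus the carrier-posterior columns.
#' @export
cohort_predictions <- function(peds, cov, mparams, bparams, tau = 5,
                               validate = TRUE) {
  if (validate) peds <- validate_pedigrees(peds, a_max = mparams$a_max)
  cov <- derive_family_covariates(peds, cov)
  post <- carrier_posteriors(peds, mparams, validate = FALSE)
  cov <- cov[match(post$family_id, cov$family_id), ]
  cz <- peds[peds$is_counselee == 1L, ]
  cz <- cz[match(post$family_id, cz$family_id), ]
  a0 <- cz$age_baseline

  class_risks <- vapply(CARRIER_CLASSES, function(cl) {
    genotype_future_risk(a0, tau, cl, mparams)
  }, numeric(length(a0)))
  if (is.null(dim(class_risks))) class_risks <- matrix(class_risks, nrow = 1)
  p_brcapro <- rowSums(
    as.matrix(post[, c("p_none", "p_brca1", "p_brca2", "p_both")]) * class_risks)

  p_bcrat <- bcrat_absolute_risk(cov, a0, tau, bparams)$risk

  rr <- relative_hazard(cov, bparams)
  p_bbm <- bbm_risk_vec(a0, tau, post, rr, mparams, bparams)

  dplyr::bind_cols(
    tibble::tibble(family_id = post$family_id, age_baseline = a0,
                   p_brcapro = p_brcapro, p_bcrat = p_bcrat, p_bbm = p_bbm),
    post[, c("p_none", "p_brca1", "p_brca2", "p_both")]
  )
}

#' Write model predictions to CSV
#'
#' Long format: `family_id`, `model`, `tau`, `risk`.
#'
#' @param preds Output of [cohort_predictions()].
#' @param tau The horizon the predictions refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, tau, path) {
  long <- tidyr::pivot_longer(
    preds[, c("family_id", "p_brcapro", "p_bcrat", "p_bbm")],
    cols = -"family_id", names_to = "model", values_to = "risk",
    names_prefix = "p_")
  long$tau <- tau
  readr::write_csv(long[, c("family_id", "model", "tau", "risk")], path)
  invisible(path)
}
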
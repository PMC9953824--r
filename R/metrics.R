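# Censoring-aware evaluation suite: IPCW weights from a (possibly
# stratified) Kaplan-Meier fit to the censoring distribution, five binary
# performance measures, decile calibration with Wilson intervals, and
# time-to-event counterparts (truncated concordance, competing-risks
# logarithmic score).

#' Inverse-probability-of-censoring weights for a tau-year binary outcome
#'
#' Subjects whose tau-year outcome is known -- diagnosed by `tau`, followed
#' event-free to `tau`, or dead before `tau` without a diagnosis -- receive
#' weight `1 / G(min(tau, T)-)`, where `G` is the Kaplan-Meier estimate of
#' the censoring distribution (fitted per stratum when `strata` is given,
#' using the censored subjects). Subjects censored before `tau` receive
#' weight 0 and a missing outcome.
#'
#' @param time Follow-up time in years (positive).
#' @param cause Event indicator: `"none"` (censored), `"bc"`, `"death"`.
#' @param tau Outcome horizon.
#' @param strata Optional stratum labels for the censoring fit.
#' @return A tibble with `y` (0/1/NA) and `weight`.
#' @export
censoring_weights <- function(time, cause, tau, strata = NULL) {
  if (any(time <= 0)) abort_combrisk("times must be positive", "combrisk_domain_error")
  if (!all(cause %in% c("none", "bc", "death"))) {
    abort_combrisk("cause must be 'none', 'bc' or 'death'", "combrisk_coding_error")
  }
  n <- length(time)
  strata <- strata %||% rep(1L, n)
  y <- rep(NA_integer_, n)
  t_eval <- rep(NA_real_, n)
  known_case <- cause == "bc" & time <= tau
  known_ctrl <- time >= tau & !known_case
  known_dead <- cause == "death" & time < tau
  y[known_case] <- 1L
  y[known_ctrl | known_dead] <- 0L
  t_eval[known_case] <- time[known_case]
  t_eval[known_ctrl] <- tau
  t_eval[known_dead] <- time[known_dead]
  w <- rep(0, n)
  for (s in unique(strata)) {
    rows <- strata == s
    cens <- as.integer(cause[rows] == "none")
    if (!any(cens == 1)) {
      G_t <- rep(1, sum(rows & !is.na(y)))
      w[rows & !is.na(y)] <- 1
      next
    }
    fit <- survival::survfit(survival::Surv(time[rows], cens) ~ 1)
    need <- rows & !is.na(y)
    G <- km_left(fit$time[fit$n.event > 0], fit$surv[fit$n.event > 0], t_eval[need])
    if (any(G <= 0)) {
      abort_combrisk("censoring survival estimated as 0 at a needed time (positivity violated)",
                     "combrisk_positivity_error")
    }
    w[need] <- 1 / G
  }
  tibble::tibble(y = y, weight = w)
}

weighted_oe <- function(pred, y, w) sum(w * y) / sum(w * pred)

weighted_auc <- function(pred, y, w) {
  if (sum(w * y) == 0 || sum(w * (1 - y)) == 0) {
    abort_combrisk("AUC undefined: need at least one case and one non-case",
                   "combrisk_degenerate_error")
  }
  o <- order(pred)
  p <- pred[o]; yy <- y[o]; ww <- w[o]
  g <- cumsum(!duplicated(p))
  w1 <- rowsum(ww * yy, g)[, 1]
  w0 <- rowsum(ww * (1 - yy), g)[, 1]
  below0 <- cumsum(w0) - w0
  sum(w1 * (below0 + 0.5 * w0)) / (sum(w1) * sum(w0))
}

#' Binary performance measures under censoring weights
#'
#' Computes the five measures for a tau-year binary outcome: the ratio of
#' observed to expected events (E is the weighted sum of predicted
#' probabilities), the IPCW area under the ROC curve (ties count one
#' half), the Brier score (weighted mean squared error), the logarithmic
#' score (weighted negative log-likelihood), and the standardized net
#' benefit at the supplied high-risk threshold:
#' `SNB = TPR - (p_t / (1 - p_t)) * ((1 - rho) / rho) * FPR`, with `rho`
#' the weighted outcome prevalence.
#'
#' @param pred Predicted probabilities.
#' @param y Outcomes (0/1; NA rows must carry weight 0).
#' @param weights Censoring (or other) weights; default 1.
#' @param threshold High-risk threshold for SNB (default 0.0167).
#' @return A one-row tibble with `o_e`, `auc`, `brier`, `log_score`, `snb`,
#'   `n_eff`.
#' @export
binary_performance <- function(pred, y, weights = NULL, threshold = 0.0167) {
  w <- weights %||% rep(1, length(pred))
  keep <- w > 0
  pred <- pred[keep]; y <- y[keep]; w <- w[keep]
  if (any(is.na(y))) abort_combrisk("positive-weight rows must have known outcomes",
                                    "combrisk_domain_error")
  assert_prob(pred, "pred")
  if (any(pred <= 0 | pred >= 1)) {
    abort_combrisk("predictions must lie strictly inside (0,1) for the logarithmic score",
                   "combrisk_domain_error")
  }
  rho <- sum(w * y) / sum(w)
  tpr <- sum(w * y * (pred >= threshold)) / sum(w * y)
  fpr <- sum(w * (1 - y) * (pred >= threshold)) / sum(w * (1 - y))
  snb <- tpr - (threshold / (1 - threshold)) * ((1 - rho) / rho) * fpr
  tibble::tibble(
    o_e = weighted_oe(pred, y, w),
    auc = weighted_auc(pred, y, w),
    brier = sum(w * (pred - y)^2) / sum(w),
    log_score = -sum(w * (y * log(pred) + (1 - y) * log(1 - pred))) / sum(w),
    snb = snb,
    n_eff = sum(w)
  )
}

#' Decile calibration table
#'
#' Cuts the cohort into bins of predicted risk and reports, per bin, the
#' weighted mean prediction, the weighted observed event proportion, and a
#' 95% Wilson interval computed on the weighted count as the effective
#' sample size.
#'
#' @param pred,y,weights As in [binary_performance()].
#' @param bins Number of bins (default 10). If there are fewer distinct
#'   prediction values than `bins`, a warning is raised and the bin count
#'   falls back to the number of distinct values (at least 2).
#' @return A tibble of class `combrisk_calibration`.
#' @export
calibration_deciles <- function(pred, y, weights = NULL, bins = 10) {
  w <- weights %||% rep(1, length(pred))
  keep <- w > 0
  pred <- pred[keep]; y <- y[keep]; w <- w[keep]
  nd <- length(unique(pred))
  if (nd < bins) {
    if (nd < 2) abort_combrisk("cannot bin: fewer than 2 distinct predictions",
                               "combrisk_binning_error")
    rlang::warn(sprintf("only %d distinct predictions; falling back to %d bins", nd, nd),
                class = "combrisk_binning_warning")
    bins <- nd
  }
  bin <- dplyr::ntile(rank(pred, ties.method = "first"), bins)
  z <- stats::qnorm(0.975)
  out <- purrr::map_dfr(seq_len(bins), function(b) {
    rows <- bin == b
    wn <- sum(w[rows])
    p_obs <- sum(w[rows] * y[rows]) / wn
    centre <- (p_obs + z^2 / (2 * wn)) / (1 + z^2 / wn)
    half <- z * sqrt(p_obs * (1 - p_obs) / wn + z^2 / (4 * wn^2)) / (1 + z^2 / wn)
    tibble::tibble(bin = b,
                   mean_pred = sum(w[rows] * pred[rows]) / wn,
                   observed = p_obs, n_eff = wn,
                   lower = max(centre - half, 0), upper = min(centre + half, 1))
  })
  class(out) <- c("combrisk_calibration", class(out))
  out
}

#' Truncated time-to-event concordance with perturbation interval
#'
#' IPCW-weighted probability that, among comparable pairs within the
#' truncation horizon, the subject with the shorter time to breast cancer
#' has the higher score. Pairs (i, j) are comparable when subject i has an
#' event at `T_i < min(T_j, tau_trunc)`; each pair is weighted by
#' `1 / G(T_i-)^2` with `G` the Kaplan-Meier censoring survival. The 95%
#' interval uses perturbation resampling with unit-mean exponential
#' multipliers.
#'
#' @param scores Risk scores (higher = predicted earlier event).
#' @param time Follow-up times.
#' @param event 1 if breast cancer observed, 0 otherwise (death or
#'   censoring).
#' @param tau_trunc Truncation horizon (default 10).
#' @param n_perturb Number of perturbation replicates (default 500).
#' @param seed Seed for the multipliers.
#' @return A one-row tibble with `c_stat`, `lower`, `upper`, `n_pairs`.
#' @export
tte_cstat <- function(scores, time, event, tau_trunc = 10,
                      n_perturb = 500, seed = 1) {
  n <- length(scores)
  cens <- as.integer(event == 0)
  G <- if (any(cens == 1)) {
    fit <- survival::survfit(survival::Surv(time, cens) ~ 1)
    km_left(fit$time[fit$n.event > 0], fit$surv[fit$n.event > 0], time)
  } else rep(1, n)
  i_ev <- which(event == 1 & time < tau_trunc)
  if (length(i_ev) == 0) abort_combrisk("no comparable pairs", "combrisk_degenerate_error")
  # pair weights and concordance indicators (event subjects as rows)
  comp <- outer(time[i_ev], time, "<")
  if (!any(comp)) abort_combrisk("no comparable pairs", "combrisk_degenerate_error")
  wi <- 1 / G[i_ev]^2
  conc <- (outer(scores[i_ev], scores, ">") + 0.5 * outer(scores[i_ev], scores, "==")) * comp
  A <- conc * wi          # numerator contributions, rows weighted
  Bm <- comp * wi
  c_hat <- sum(A) / sum(Bm)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  reps <- vapply(seq_len(n_perturb), function(b) {
    xi <- stats::rexp(n)
    num <- drop(xi[i_ev] %*% A %*% xi)
    den <- drop(xi[i_ev] %*% Bm %*% xi)
    num / den
  }, numeric(1))
  tibble::tibble(c_stat = c_hat,
                 lower = stats::quantile(reps, 0.025, names = FALSE),
                 upper = stats::quantile(reps, 0.975, names = FALSE),
                 n_pairs = sum(comp))
}

#' Competing-risks logarithmic score for discrete time-to-event predictions
#'
#' Each subject carries a predicted discrete distribution over (year,
#' cause) pairs. The score is the negative mean log of the predicted mass
#' at the observed (year, cause) for subjects with an event, and of the
#' predicted overall survival past the censoring year for censored
#' subjects. Zero predicted mass at an observed outcome yields an infinite
#' score and a warning (reported, not thrown).
#'
#' @param pred_dist Array `n x horizon x 2`; `pred_dist[i, t, k]` is the
#'   predicted probability that subject i fails from cause k (1 = breast
#'   cancer, 2 = death) in year t. Row sums must not exceed 1.
#' @param time Observed whole-year times.
#' @param cause `"none"`, `"bc"`, or `"death"`.
#' @return A one-row tibble with `log_score` and `n`.
#' @export
tte_log_score <- function(pred_dist, time, cause) {
  stopifnot(length(dim(pred_dist)) == 3, dim(pred_dist)[3] == 2)
  n <- dim(pred_dist)[1]
  horizon <- dim(pred_dist)[2]
  if (any(time > horizon)) abort_combrisk("time beyond prediction horizon",
                                          "combrisk_range_error")
  lik <- rep(NA_real_, n)
  t_int <- as.integer(floor(time))
  for (i in seq_len(n)) {
    if (cause[i] == "bc") {
      lik[i] <- pred_dist[i, t_int[i], 1]
    } else if (cause[i] == "death") {
      lik[i] <- pred_dist[i, t_int[i], 2]
    } else {
      surv <- 1 - sum(pred_dist[i, seq_len(t_int[i]), ])
      lik[i] <- max(surv, 0)
    }
  }
  if (any(lik == 0)) {
    rlang::warn("zero predicted mass at an observed outcome: infinite logarithmic score",
                class = "combrisk_zero_mass_warning")
  }
  tibble::tibble(log_score = -mean(log(lik)), n = n)
}

#' Observed/expected ratio over individual follow-up horizons
#'
#' For the time-to-event outcome the expected count sums each counselee's
#' predicted risk up to the end of her own follow-up time.
#'
#' @param pred_to_followup Predicted probability of the event by the end of
#'   each subject's own follow-up.
#' @param event 1 if the event was observed during follow-up.
#' @return The O/E ratio.
#' @export
oe_followup <- function(pred_to_followup, event) {
  sum(event) / sum(pred_to_followup)
}
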
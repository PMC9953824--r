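# Bootstrap confidence intervals and pairwise model comparisons for the
# binary performance measures.

METRIC_NAMES <- c("o_e", "auc", "brier", "log_score", "snb")

# Is value a better than value b for this metric?
metric_better <- function(metric, a, b) {
  switch(metric,
         o_e = abs(log(a)) < abs(log(b)),
         auc = a > b,
         snb = a > b,
         brier = a < b,
         log_score = a < b)
}

#' Bootstrap comparison of risk models
#'
#' Resamples counselees with replacement, recomputes the five binary
#' performance measures for every model in each replicate (censoring
#' weights are re-estimated within the replicate), and reports percentile
#' confidence intervals together with the pairwise win proportions: the
#' fraction of replicates in which model A strictly outperformed model B
#' on each metric (higher AUC/SNB, lower Brier/logarithmic score, O/E
#' closer to 1 on the log scale). Replicates without any observed case are
#' dropped and counted.
#'
#' @param data Tibble with one row per counselee: one prediction column per
#'   model plus `time` and `cause` (and optionally a `stratum` column for
#'   the censoring fit).
#' @param models Names of the prediction columns to compare.
#' @param tau Outcome horizon.
#' @param threshold SNB high-risk threshold.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @return A list of class `combrisk_comparison`: `estimates` (point
#'   estimates with 95% CIs), `wins` (pairwise win proportions), `B_used`,
#'   `B_dropped`.
#' @export
bootstrap_compare <- function(data, models, tau = 5, threshold = 0.0167,
                              B = 1000, seed = 1) {
  if (B < 2) abort_combrisk("B must be at least 2", "combrisk_domain_error")
  stopifnot(all(models %in% names(data)))
  strata <- if ("stratum" %in% names(data)) data$stratum else NULL
  eval_once <- function(rows) {
    cw <- censoring_weights(data$time[rows], data$cause[rows], tau,
                            strata = if (is.null(strata)) NULL else strata[rows])
    if (sum(cw$weight * (!is.na(cw$y) & cw$y == 1L)) == 0) return(NULL)
    vapply(models, function(m) {
      as.numeric(binary_performance(data[[m]][rows], cw$y, cw$weight,
                                    threshold)[, METRIC_NAMES])
    }, numeric(length(METRIC_NAMES)))
  }
  n <- nrow(data)
  point <- eval_once(seq_len(n))
  if (is.null(point)) abort_combrisk("no cases in the cohort", "combrisk_degenerate_error")
  rownames(point) <- METRIC_NAMES

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  reps <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    r <- eval_once(sample.int(n, n, replace = TRUE))
    if (is.null(r)) dropped <- dropped + 1L else reps[[b]] <- r
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  arr <- simplify2array(reps)  # metric x model x replicate

  estimates <- purrr::map_dfr(seq_along(models), function(j) {
    purrr::map_dfr(seq_along(METRIC_NAMES), function(i) {
      tibble::tibble(model = models[j], metric = METRIC_NAMES[i],
                     estimate = point[i, j],
                     lower = stats::quantile(arr[i, j, ], 0.025, names = FALSE),
                     upper = stats::quantile(arr[i, j, ], 0.975, names = FALSE))
    })
  })
  pairs <- expand.grid(a = models, b = models, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  wins <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- pairs$a[k]; b <- pairs$b[k]
    ja <- match(a, models); jb <- match(b, models)
    purrr::map_dfr(seq_along(METRIC_NAMES), function(i) {
      m <- METRIC_NAMES[i]
      tibble::tibble(model_a = a, model_b = b, metric = m,
                     win_prop = mean(metric_better(m, arr[i, ja, ], arr[i, jb, ])))
    })
  })
  structure(list(estimates = estimates, wins = wins,
                 B_used = length(reps), B_dropped = dropped),
            class = "combrisk_comparison")
}

#' @export
print.combrisk_comparison <- function(x, ...) {
  cat("<combrisk_comparison>", x$B_used, "replicates (", x$B_dropped, "dropped )\n")
  print(tidyr::pivot_wider(x$estimates, names_from = "metric",
                           values_from = c("estimate", "lower", "upper")))
  invisible(x)
}

#' Full evaluation report for a prediction table
#'
#' Convenience wrapper producing the point estimates, bootstrap CIs,
#' pairwise comparisons and decile calibration tables for a set of models
#' on one cohort.
#'
#' @inheritParams bootstrap_compare
#' @param bins Calibration bins.
#' @return A list with `comparison` (see [bootstrap_compare()]) and
#'   `calibration` (one `combrisk_calibration` per model).
#' @export
performance_report <- function(data, models, tau = 5, threshold = 0.0167,
                               B = 1000, seed = 1, bins = 10) {
  comp <- bootstrap_compare(data, models, tau, threshold, B, seed)
  cw <- censoring_weights(data$time, data$cause, tau,
                          strata = if ("stratum" %in% names(data)) data$stratum else NULL)
  calib <- purrr::map(stats::setNames(models, models), function(m) {
    calibration_deciles(data[[m]], cw$y, cw$weight, bins = bins)
  })
  list(comparison = comp, calibration = calib)
}
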
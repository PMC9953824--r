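# Independent textbook formulas used as oracles.
naive_auc <- function(p, y) {
  cases <- p[y == 1]; ctrls <- p[y == 0]
  s <- 0
  for (a in cases) s <- s + sum(a > ctrls) + 0.5 * sum(a == ctrls)
  s / (length(cases) * length(ctrls))
}

test_that("without censoring all weights are one and metrics match textbook formulas", {
  set.seed(701)
  n <- 400
  p <- stats::runif(n, 0.01, 0.4)
  y <- stats::rbinom(n, 1, p)
  time <- ifelse(y == 1, stats::runif(n, 0.5, 5), 5 + stats::runif(n))
  cause <- ifelse(y == 1, "bc", "none")
  cw <- censoring_weights(time, cause, tau = 5)
  expect_true(all(cw$weight == 1))
  expect_equal(cw$y, y)
  perf <- binary_performance(p, cw$y, cw$weight, threshold = 0.0167)
  expect_equal(perf$o_e, sum(y) / sum(p), tolerance = 1e-12)
  expect_equal(perf$auc, naive_auc(p, y), tolerance = 1e-12)
  expect_equal(perf$brier, mean((p - y)^2), tolerance = 1e-12)
  expect_equal(perf$log_score, -mean(y * log(p) + (1 - y) * log(1 - p)),
               tolerance = 1e-12)
  rho <- mean(y); pt <- 0.0167
  snb <- mean(p[y == 1] >= pt) - pt / (1 - pt) * (1 - rho) / rho * mean(p[y == 0] >= pt)
  expect_equal(perf$snb, snb, tolerance = 1e-12)
})

test_that("completely-at-random censoring halves the risk set and doubles the weights", {
  n <- 200
  time <- c(rep(2, 100), rep(6, 100))           # censored at 2 vs followed past tau
  cause <- rep("none", n)
  cw <- censoring_weights(time, cause, tau = 5)
  expect_true(all(cw$weight[time == 2] == 0))
  expect_true(all(is.na(cw$y[time == 2])))
  expect_equal(unique(cw$weight[time == 6]), 2)  # 1 / G(5-) with G = 0.5
  expect_equal(unique(cw$y[time == 6]), 0L)
})

test_that("stratified censoring estimation differs from the pooled fit", {
  time <- c(rep(1, 30), rep(6, 70), rep(3, 70), rep(6, 30))
  cause <- rep("none", 200)
  strat <- rep(c("a", "b"), each = 100)
  pooled <- censoring_weights(time, cause, tau = 5)
  strd <- censoring_weights(time, cause, tau = 5, strata = strat)
  expect_false(isTRUE(all.equal(pooled$weight, strd$weight)))
  # per-stratum censoring survival at 5-: 0.7 in stratum a, 0.3 in stratum b
  expect_equal(unique(strd$weight[time == 6 & strat == "a"]), 1 / 0.7)
  expect_equal(unique(strd$weight[time == 6 & strat == "b"]), 1 / 0.3)
})

test_that("deaths before tau count as known non-cases", {
  time <- c(1.5, 2, 6, 6)
  cause <- c("death", "bc", "none", "none")
  cw <- censoring_weights(time, cause, tau = 5)
  expect_equal(cw$y, c(0L, 1L, 0L, 0L))
  expect_true(all(cw$weight == 1))
})

test_that("a four-row fixture with a tie and a censored subject matches brute force", {
  p <- c(0.10, 0.10, 0.30, 0.20)
  time <- c(6, 2.5, 1.0, 3.0)
  cause <- c("none", "bc", "bc", "none")  # last censored before tau
  cw <- censoring_weights(time, cause, tau = 5)
  w <- cw$weight; y <- cw$y
  keep <- w > 0
  # hand KM of censoring: censoring event at 3 with 2 at risk -> G = 0.5
  expect_equal(w[keep], c(1 / 0.5, 1, 1))
  perf <- binary_performance(p[keep], y[keep], w[keep], threshold = 0.15)
  expect_equal(perf$o_e, sum(w[keep] * y[keep]) / sum(w[keep] * p[keep]))
  num <- 0; den <- 0
  for (i in which(keep & y == 1)) {
    for (j in which(keep & y == 0)) {
      den <- den + w[i] * w[j]
      num <- num + w[i] * w[j] * ((p[i] > p[j]) + 0.5 * (p[i] == p[j]))
    }
  }
  expect_equal(perf$auc, num / den, tolerance = 1e-12)
  expect_equal(perf$brier, sum(w[keep] * (p[keep] - y[keep])^2) / sum(w[keep]))
})

test_that("AUC is invariant under monotone transforms; SNB of a perfect predictor is one", {
  set.seed(702)
  p <- stats::runif(300, 0.01, 0.5)
  y <- stats::rbinom(300, 1, p)
  w <- rep(1, 300)
  a1 <- binary_performance(p, y, w)$auc
  a2 <- binary_performance(stats::plogis(5 * stats::qlogis(p)), y, w)$auc
  expect_equal(a1, a2, tolerance = 1e-12)

  sep <- c(rep(0.9, 10), rep(0.05, 30))
  ysep <- c(rep(1, 10), rep(0, 30))
  perf <- binary_performance(sep, ysep, rep(1, 40), threshold = 0.5)
  expect_equal(perf$auc, 1)
  expect_equal(perf$snb, 1)
  expect_error(binary_performance(sep, rep(0, 40), rep(1, 40)),
               class = "combrisk_degenerate_error")
})

test_that("decile calibration covers a calibrated cohort and is rank-based", {
  set.seed(703)
  p <- stats::runif(50000, 0.02, 0.6)
  y <- stats::rbinom(50000, 1, p)
  cal <- calibration_deciles(p, y)
  expect_equal(nrow(cal), 10L)
  expect_true(all(cal$lower <= cal$mean_pred & cal$mean_pred <= cal$upper))

  # decile membership is invariant to a monotone transform of predictions
  cal2 <- calibration_deciles(p^2, y)
  expect_equal(cal$observed, cal2$observed, tolerance = 1e-12)

  # constant outcome 0: observed proportions 0, Wilson lower bound 0
  cal0 <- calibration_deciles(p[1:100], rep(0L, 100))
  expect_true(all(cal0$observed == 0))
  expect_lt(max(cal0$lower), 1e-12)

  expect_warning(calibration_deciles(rep(c(0.1, 0.2, 0.3), 20),
                                     stats::rbinom(60, 1, 0.2)),
                 class = "combrisk_binning_warning")
  expect_error(calibration_deciles(rep(0.1, 30), stats::rbinom(30, 1, 0.2)),
               class = "combrisk_binning_error")
})

test_that("the truncated concordance handles perfect, random, and uncensored data", {
  set.seed(704)
  n <- 300
  time <- stats::rexp(n, 0.15)
  event <- rep(1L, n)
  res <- tte_cstat(-time, time, event, tau_trunc = 10, n_perturb = 100, seed = 1)
  expect_equal(res$c_stat, 1)

  scores <- stats::rnorm(1500)
  time2 <- stats::rexp(1500, 0.15)
  ev2 <- stats::rbinom(1500, 1, 0.8)
  res2 <- tte_cstat(scores, time2, ev2, tau_trunc = 10, n_perturb = 100, seed = 2)
  se <- (res2$upper - res2$lower) / (2 * 1.96)
  expect_lt(abs(res2$c_stat - 0.5), 3 * se)
  expect_true(res2$lower <= res2$c_stat && res2$c_stat <= res2$upper)

  # uncensored data: matches the O(n^2) comparable-pair count
  sc <- stats::rnorm(n)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (time[i] >= 10) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        den <- den + 1
        num <- num + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
      }
    }
  }
  res3 <- tte_cstat(sc, time, event, tau_trunc = 10, n_perturb = 50, seed = 3)
  expect_equal(res3$c_stat, num / den, tolerance = 1e-12)
  expect_error(tte_cstat(sc[1:5], rep(20, 5), rep(1L, 5), tau_trunc = 10),
               class = "combrisk_degenerate_error")
})

test_that("the competing-risks log score reduces to binary log loss in one period", {
  p <- c(0.2, 0.7, 0.1)
  pred <- array(0, dim = c(3, 1, 2))
  pred[, 1, 1] <- p
  time <- c(1, 1, 1)
  cause <- c("bc", "none", "bc")
  res <- tte_log_score(pred, time, cause)
  want <- -mean(c(log(0.2), log(1 - 0.7), log(0.1)))
  expect_equal(res$log_score, want, tolerance = 1e-12)
  # zero mass at an observed event warns and reports Inf
  pred0 <- pred; pred0[3, 1, 1] <- 0
  expect_warning(res0 <- tte_log_score(pred0, time, cause),
                 class = "combrisk_zero_mass_warning")
  expect_equal(res0$log_score, Inf)
})

test_that("the competing-risks log score is proper on synthetic data", {
  set.seed(705)
  n <- 10000; horizon <- 6
  p_bc <- c(0.03, 0.04, 0.05, 0.04, 0.03, 0.02)
  p_d <- rep(0.02, horizon)
  truth <- array(0, dim = c(n, horizon, 2))
  for (t in seq_len(horizon)) {
    truth[, t, 1] <- p_bc[t]; truth[, t, 2] <- p_d[t]
  }
  # draw outcomes from the true discrete distribution
  pmat <- cbind(matrix(c(rbind(p_bc, p_d)), n, 2 * horizon, byrow = TRUE),
                1 - sum(p_bc) - sum(p_d))
  pick <- apply(pmat, 1, function(pr) sample.int(length(pr), 1, prob = pr))
  time <- ifelse(pick > 2 * horizon, horizon, ceiling(pick / 2))
  cause <- ifelse(pick > 2 * horizon, "none", ifelse(pick %% 2 == 1, "bc", "death"))
  s_true <- tte_log_score(truth, time, cause)$log_score
  shift <- truth
  shift[, , 1] <- pmin(truth[, , 1] * 2, 0.2)
  s_bad <- tte_log_score(shift, time, cause)$log_score
  expect_lt(s_true, s_bad)
})

test_that("follow-up O/E matches a hand sum on a three-subject fixture", {
  pred <- c(0.10, 0.05, 0.20)
  event <- c(1, 0, 0)
  expect_equal(oe_followup(pred, event), 1 / 0.35)
})

test_that("bootstrap comparison is deterministic, self-consistent, and drops empty replicates", {
  set.seed(706)
  n <- 500
  p <- stats::runif(n, 0.02, 0.4)
  y <- stats::rbinom(n, 1, p)
  d <- tibble::tibble(
    m1 = p, m2 = pmin(pmax(p + stats::rnorm(n, 0, 0.05), 0.001), 0.99),
    time = ifelse(y == 1, stats::runif(n, 0.5, 4.5), 5.5),
    cause = ifelse(y == 1, "bc", "none"))
  c1 <- bootstrap_compare(d, c("m1", "m2"), tau = 5, B = 50, seed = 9)
  c2 <- bootstrap_compare(d, c("m1", "m2"), tau = 5, B = 50, seed = 9)
  expect_identical(c1$estimates, c2$estimates)
  expect_identical(c1$wins, c2$wins)

  # a model never strictly beats itself
  c3 <- bootstrap_compare(dplyr::mutate(d, m3 = .data$m1), c("m1", "m3"),
                          tau = 5, B = 20, seed = 3)
  expect_true(all(c3$wins$win_prop == 0))

  # replicates without cases are dropped and counted
  d_small <- d[c(which(y == 1)[1], which(y == 0)[1:6]), ]
  c4 <- bootstrap_compare(d_small, "m1", tau = 5, B = 100, seed = 4)
  expect_gt(c4$B_dropped, 0)
  expect_equal(c4$B_used + c4$B_dropped, 100L)

  # CIs contain the point estimates
  ok <- with(c1$estimates, lower <= estimate & estimate <= upper)
  expect_true(all(ok))
})

test_that("autoplot methods return ggplot objects", {
  set.seed(707)
  p <- stats::runif(200, 0.02, 0.5)
  y <- stats::rbinom(200, 1, p)
  cal <- calibration_deciles(p, y)
  expect_s3_class(autoplot(cal), "ggplot")
  d <- tibble::tibble(m1 = p, m2 = p,
                      time = ifelse(y == 1, 2, 6),
                      cause = ifelse(y == 1, "bc", "none"))
  cmp <- bootstrap_compare(d, c("m1", "m2"), tau = 5, B = 10, seed = 2)
  expect_s3_class(autoplot(cmp), "ggplot")
})
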
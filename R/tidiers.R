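# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stacked logistic ensemble
#'
#' @param x A `stacked_logistic` model.
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @exportS3Method generics::tidy
tidy.stacked_logistic <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "sqrt_p_brcapro", "sqrt_p_bcrat", "product")[
    match(rownames(s), c("(Intercept)", "x1", "x2", "x3"))],
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.stacked_logistic
#' @exportS3Method generics::glance
glance.stacked_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, tau = x$tau,
                 weighted = x$weighted, converged = x$fit$converged,
                 deviance = x$fit$deviance, aic = x$fit$aic)
}

#' Tidy a stacked Fine-Gray ensemble
#'
#' @param x A `stacked_finegray` model.
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @exportS3Method generics::tidy
tidy.stacked_finegray <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("sqrt_p_brcapro", "sqrt_p_bcrat", "product")[
    match(rownames(s), c("x1", "x2", "x3"))],
    estimate = s[, "coef"], std.error = s[, "se(coef)"],
    statistic = s[, "z"], p.value = s[, "Pr(>|z|)"])
}

#' @rdname tidy.stacked_finegray
#' @exportS3Method generics::glance
glance.stacked_finegray <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, tau_star = x$tau_star,
                 weighted = x$weighted,
                 concordance = unname(x$fit$concordance["concordance"]))
}

#' @exportS3Method generics::glance
glance.density_ratio <- function(x, ...) {
  tibble::tibble(n_centers = nrow(x$centers), sigma = x$sigma,
                 lambda = x$lambda, cv_score = x$cv_score)
}

#' Calibration plot
#'
#' Observed event proportion (with 95% Wilson interval) against mean
#' predicted probability per risk bin, with the identity line.
#'
#' @param object A `combrisk_calibration` table from
#'   [calibration_deciles()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.combrisk_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_pred, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed proportion (95% Wilson CI)") +
    ggplot2::theme_minimal()
}

#' Pairwise win-proportion plot
#'
#' Heatmap of the proportion of bootstrap replicates in which the row
#' model outperformed the column model, per metric.
#'
#' @param object A `combrisk_comparison` from [bootstrap_compare()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.combrisk_comparison <- function(object, ...) {
  ggplot2::ggplot(object$wins,
                  ggplot2::aes(x = .data$model_b, y = .data$model_a,
                               fill = .data$win_prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$win_prop)),
                       size = 3) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "firebrick",
                                  high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "model B", y = "model A", fill = "P(A beats B)") +
    ggplot2::theme_minimal()
}
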
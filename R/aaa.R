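# Internal helpers shared across modules.

CARRIER_CLASSES <- c("none", "brca1", "brca2", "both")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_combrisk <- function(msg, class) {
  rlang::abort(msg, class = c(class, "combrisk_error"))
}

# Truncated normal draw (lower bound only), vectorised.
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

# Left-continuous evaluation G(t-) of a Kaplan-Meier step function.
km_left <- function(fit_times, fit_surv, t) {
  if (length(fit_times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, fit_times, left.open = TRUE)
  c(1, fit_surv)[idx + 1L]
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort_combrisk(sprintf("`%s` must lie in [0, 1].", name), "combrisk_domain_error")
  }
  invisible(x)
}
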
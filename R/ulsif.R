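# Least-squares importance fitting (uLSIF): a Gaussian-kernel linear model
# for the density ratio target/train, fitted by ridge-regularised least
# squares in closed form, with (bandwidth, ridge) chosen by cross-validated
# squared-error criterion and negative coefficients truncated to zero.

gauss_kernel <- function(X, C, sigma) {
  # ||x - c||^2 via the expansion, rows of X vs rows of C
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Fit a density-ratio model by least-squares importance fitting
#'
#' Models the ratio of the target to the training covariate density as a
#' nonnegative combination of Gaussian kernels centred on a subset of
#' target rows. Coefficients solve the regularised least-squares system in
#' closed form; the bandwidth and ridge penalty are chosen by k-fold
#' cross-validation of the squared-error criterion
#' `J = 1/2 E_train[w(x)^2] - E_target[w(x)]`, and negative coefficients
#' are truncated to zero.
#'
#' @param train_features,target_features Data frames (or matrices) with the
#'   same numeric feature columns; at least 2 rows each.
#' @param bandwidth_grid Multipliers of the median-heuristic bandwidth,
#'   spanning 1/4 to 4 in half-octave steps by default.
#' @param ridge_grid Ridge penalties, spanning 1e-3 to 10 in half-decade
#'   steps by default.
#' @param n_centers Number of kernel centres sampled from the target rows
#'   (default `min(100, nrow(target))`).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling centre sampling and fold
#'   assignment.
#' @return An object of class `density_ratio`.
#' @export
fit_density_ratio <- function(train_features, target_features,
                              bandwidth_grid = 2^seq(-2, 2, by = 0.5),
                              ridge_grid = 10^seq(-3, 1, by = 0.5),
                              n_centers = 100,
                              n_folds = 5,
                              seed = 1) {
  Xtr <- as.matrix(train_features)
  Xte <- as.matrix(target_features)
  if (!identical(colnames(Xtr), colnames(Xte))) {
    abort_combrisk("train and target feature columns must match", "combrisk_schema_error")
  }
  if (nrow(Xtr) < 2 || nrow(Xte) < 2) {
    abort_combrisk("need at least 2 rows in each sample", "combrisk_data_error")
  }
  if (any(!is.finite(Xtr)) || any(!is.finite(Xte))) {
    abort_combrisk("features must be finite", "combrisk_data_error")
  }
  # standardise on the pooled sample so bandwidths are comparable per axis
  pooled <- rbind(Xtr, Xte)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, stats::sd)
  scl[scl == 0] <- 1
  Ztr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  Zte <- sweep(sweep(Xte, 2, ctr), 2, scl, "/")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  n_centers <- min(n_centers, nrow(Zte))
  centers <- Zte[sample.int(nrow(Zte), n_centers), , drop = FALSE]

  # median-heuristic base bandwidth on a pooled subsample
  sub <- rbind(Ztr, Zte)
  if (nrow(sub) > 500) sub <- sub[sample.int(nrow(sub), 500), , drop = FALSE]
  d <- stats::dist(sub)
  sigma0 <- stats::median(d[d > 0])
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 1

  fold_tr <- sample(rep_len(seq_len(n_folds), nrow(Ztr)))
  fold_te <- sample(rep_len(seq_len(n_folds), nrow(Zte)))

  best <- list(score = Inf)
  for (bw in bandwidth_grid) {
    sigma <- sigma0 * bw
    Ktr <- gauss_kernel(Ztr, centers, sigma)
    Kte <- gauss_kernel(Zte, centers, sigma)
    H_all <- crossprod(Ktr) / nrow(Ktr)
    h_all <- colMeans(Kte)
    for (lam in ridge_grid) {
      score <- 0
      singular <- FALSE
      for (fd in seq_len(n_folds)) {
        tr_in <- fold_tr != fd; te_in <- fold_te != fd
        H <- crossprod(Ktr[tr_in, , drop = FALSE]) / sum(tr_in)
        h <- colMeans(Kte[te_in, , drop = FALSE])
        alpha <- tryCatch(solve(H + lam * diag(n_centers), h),
                          error = function(e) NULL)
        if (is.null(alpha)) { singular <- TRUE; break }
        # score the truncated (nonnegative) solution: the raw solution of an
        # ill-conditioned system can fake a low held-out objective through
        # cancelling oscillations
        alpha <- pmax(alpha, 0)
        Ho <- crossprod(Ktr[!tr_in, , drop = FALSE]) / sum(!tr_in)
        ho <- colMeans(Kte[!te_in, , drop = FALSE])
        score <- score + 0.5 * drop(t(alpha) %*% Ho %*% alpha) - drop(ho %*% alpha)
      }
      if (singular) next
      score <- score / n_folds
      if (score < best$score) {
        alpha_full <- tryCatch(solve(H_all + lam * diag(n_centers), h_all),
                               error = function(e) NULL)
        if (is.null(alpha_full)) next
        best <- list(score = score, sigma = sigma, lambda = lam,
                     alpha = pmax(alpha_full, 0))
      }
    }
  }
  if (!is.finite(best$score)) {
    abort_combrisk("density-ratio system singular at every grid point",
                   "combrisk_fit_error")
  }
  structure(list(centers = centers, sigma = best$sigma, lambda = best$lambda,
                 alpha = best$alpha, cv_score = best$score,
                 features = colnames(Xtr), center_ctr = ctr, center_scl = scl,
                 seed = seed),
            class = "density_ratio")
}

#' Importance weights for training rows
#'
#' Evaluates the fitted density-ratio (importance weight) function at
#' training rows. Weights are nonnegative by construction; optionally they
#' are renormalised to mean 1 (recorded in the `renormalized` attribute).
#'
#' @param object A `density_ratio` model.
#' @param train_features Data frame with the model's feature columns.
#' @param renormalize Rescale weights to mean 1 (default FALSE).
#' @return A numeric vector of nonnegative weights with attribute
#'   `renormalized`.
#' @export
training_weights <- function(object, train_features, renormalize = FALSE) {
  X <- as.matrix(train_features)
  if (!identical(colnames(X), object$features)) {
    abort_combrisk("feature columns do not match the fitted model",
                   "combrisk_schema_error")
  }
  Z <- sweep(sweep(X, 2, object$center_ctr), 2, object$center_scl, "/")
  w <- as.numeric(gauss_kernel(Z, object$centers, object$sigma) %*% object$alpha)
  w <- pmax(w, 0)
  if (renormalize) {
    m <- mean(w)
    if (m <= 0) abort_combrisk("all weights are zero; cannot renormalise",
                               "combrisk_degenerate_error")
    w <- w / m
  }
  attr(w, "renormalized") <- renormalize
  w
}

#' Serialise a density-ratio model to YAML
#'
#' Writes the kernel centres, bandwidth, ridge penalty, mixing
#' coefficients, feature list and standardisation constants.
#'
#' @param object A `density_ratio` model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_density_ratio <- function(object, path) {
  yaml::write_yaml(list(
    type = "density_ratio",
    features = object$features,
    sigma = object$sigma,
    lambda = object$lambda,
    alpha = as.numeric(object$alpha),
    centers = apply(object$centers, 1, as.numeric, simplify = FALSE),
    center_ctr = as.numeric(object$center_ctr),
    center_scl = as.numeric(object$center_scl),
    seed = object$seed
  ), path, precision = 15)
  invisible(path)
}
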
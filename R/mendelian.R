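# Exact two-gene carrier-probability computation and crude future-risk
# projection. Genotypes are tracked per gene as copy numbers {0,1,2}; the
# joint state space has 9 states, collapsed to the 4 carrier classes
# (none / brca1 / brca2 / both) only at the penetrance boundary.

# State s in 1..9 maps to copies (c1, c2) with c1 varying fastest.
STATE_C1 <- rep(0:2, times = 3)
STATE_C2 <- rep(0:2, each = 3)
STATE_CLASS <- ifelse(STATE_C1 > 0 & STATE_C2 > 0, "both",
                      ifelse(STATE_C1 > 0, "brca1",
                             ifelse(STATE_C2 > 0, "brca2", "none")))
STATE_CLASS_IDX <- match(STATE_CLASS, CARRIER_CLASSES)

# Mendelian transmission for one diallelic gene:
# child copies = Bernoulli(f/2) + Bernoulli(m/2).
transmission1 <- local({
  T1 <- array(0, dim = c(3, 3, 3))
  for (f in 0:2) for (m in 0:2) {
    pf <- f / 2; pm <- m / 2
    pr <- c((1 - pf) * (1 - pm),
            pf * (1 - pm) + (1 - pf) * pm,
            pf * pm)
    T1[, f + 1, m + 1] <- pr
  }
  T1
})

# Joint 9-state transmission array T9[child, father, mother].
transmission9 <- local({
  T9 <- array(0, dim = c(9, 9, 9))
  for (sc in 1:9) for (sf in 1:9) for (sm in 1:9) {
    T9[sc, sf, sm] <-
      transmission1[STATE_C1[sc] + 1, STATE_C1[sf] + 1, STATE_C1[sm] + 1] *
      transmission1[STATE_C2[sc] + 1, STATE_C2[sf] + 1, STATE_C2[sm] + 1]
  }
  T9
})

# Hardy-Weinberg founder prior over the 9 joint states.
hw_prior9 <- function(q1, q2) {
  p1 <- c((1 - q1)^2, 2 * q1 * (1 - q1), q1^2)
  p2 <- c((1 - q2)^2, 2 * q2 * (1 - q2), q2^2)
  p1[STATE_C1 + 1] * p2[STATE_C2 + 1]
}

# Transmission marginalised over an unobserved Hardy-Weinberg co-parent:
# M9[child, parent] = sum_m prior(m) T9[child, parent, m].
marginal_transmission9 <- function(prior9) {
  matrix(matrix(transmission9, 81, 9) %*% prior9, 9, 9)
}

# Phenotype + test-result likelihood for every member x carrier class.
# `fam` needs columns sex, age_baseline, bc_affected, bc_onset_age,
# oc_affected, oc_onset_age, test_brca1, test_brca2.
class_likelihoods <- function(fam, params) {
  pen <- params$penetrance
  n <- nrow(fam)
  lik <- matrix(1, n, 4, dimnames = list(NULL, CARRIER_CLASSES))
  cancer_factor <- function(tab_name, affected, onset, age, rows) {
    f <- pen$f[[tab_name]]; Fm <- pen$F[[tab_name]]
    out <- matrix(1, length(rows), 4)
    aff <- !is.na(affected) & affected == 1L
    unaff <- !is.na(affected) & affected == 0L
    if (any(aff)) {
      if (any(onset[aff] > pen$a_max)) {
        abort_combrisk("onset age outside penetrance table", "combrisk_range_error")
      }
      out[aff, ] <- f[onset[aff], , drop = FALSE]
    }
    if (any(unaff)) out[unaff, ] <- 1 - Fm[age[unaff], , drop = FALSE]
    out
  }
  fem <- fam$sex == "F"
  for (s in c(TRUE, FALSE)) {
    rows <- which(fem == s)
    if (length(rows) == 0) next
    tab <- if (s) "breast_female" else "breast_male"
    lik[rows, ] <- lik[rows, , drop = FALSE] *
      cancer_factor(tab, fam$bc_affected[rows], fam$bc_onset_age[rows],
                    fam$age_baseline[rows], rows)
    if (s) {
      lik[rows, ] <- lik[rows, , drop = FALSE] *
        cancer_factor("ovarian_female", fam$oc_affected[rows],
                      fam$oc_onset_age[rows], fam$age_baseline[rows], rows)
    }
  }
  # genetic tests: per-gene sensitivity/specificity on carrier status
  test_factor <- function(res, carrier_cols) {
    fac <- matrix(1, n, 4)
    pos <- !is.na(res) & res == 1L
    neg <- !is.na(res) & res == 2L
    sens <- params$test_sensitivity; spec <- params$test_specificity
    carr <- matrix(rep(carrier_cols, each = n), n, 4)
    fac[pos, ] <- ifelse(carr[pos, , drop = FALSE], sens, 1 - spec)
    fac[neg, ] <- ifelse(carr[neg, , drop = FALSE], 1 - sens, spec)
    fac
  }
  lik <- lik * test_factor(fam$test_brca1, CARRIER_CLASSES %in% c("brca1", "both"))
  lik <- lik * test_factor(fam$test_brca2, CARRIER_CLASSES %in% c("brca2", "both"))
  lik
}

#' Phenotype likelihood of one family member given a genotype
#'
#' The emission term of the pedigree likelihood: the probability of the
#' member's observed breast/ovarian phenotypes (onset at the recorded age if
#' affected; survival free of the cancer through the observation age if
#' known unaffected; 1 if status is missing) and genetic test results, given
#' a genotype. The observation age is `age_baseline` (current age if alive,
#' age at death if deceased).
#'
#' @param ind A one-row data frame in the pedigree dialect.
#' @param g A [genotype_state()].
#' @param params [mendelian_params()].
#' @return A probability.
#' @export
phenotype_likelihood <- function(ind, g, params) {
  lik <- class_likelihoods(ind, params)
  unname(lik[1, g$carrier_class])
}

# ---- Sum-product variable elimination over one family -----------------------

# Expand a factor table to the union scope `uvars` (9 states per variable).
expand_tab <- function(tab, vars, uvars) {
  nu <- length(uvars)
  a <- array(tab, dim = rep(9L, nu))
  cur <- c(vars, setdiff(uvars, vars))
  if (identical(cur, uvars)) return(a)
  aperm(a, match(uvars, cur))
}

# Exact posterior over the counselee's 9 joint states for one family.
peel_one <- function(fa, mo, counselee, emis9, prior9, M9) {
  n <- length(fa)
  factors <- vector("list", 2L * n)
  nf <- 0L
  for (i in seq_len(n)) {
    e <- emis9[i, ]
    if (is.na(fa[i]) && is.na(mo[i])) {
      e <- e * prior9
      factors[[nf <- nf + 1L]] <- list(vars = i, tab = e)
    } else if (!is.na(fa[i]) && !is.na(mo[i])) {
      factors[[nf <- nf + 1L]] <- list(vars = i, tab = e)
      factors[[nf <- nf + 1L]] <- list(vars = c(i, fa[i], mo[i]), tab = transmission9)
    } else {
      p <- if (is.na(fa[i])) mo[i] else fa[i]
      factors[[nf <- nf + 1L]] <- list(vars = i, tab = e)
      factors[[nf <- nf + 1L]] <- list(vars = c(i, p), tab = M9)
    }
  }
  factors <- factors[seq_len(nf)]
  for (v in elimination_order(fa, mo, counselee, n)) {
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1))
    fs <- factors[inv]
    uvars <- unique(unlist(lapply(fs, `[[`, "vars")))
    uvars <- c(setdiff(uvars, v), v)
    tab <- expand_tab(fs[[1]]$tab, fs[[1]]$vars, uvars)
    if (length(fs) > 1) {
      for (k in 2:length(fs)) {
        tab <- tab * expand_tab(fs[[k]]$tab, fs[[k]]$vars, uvars)
      }
    }
    nu <- length(uvars)
    dim(tab) <- c(9L^(nu - 1L), 9L)
    newf <- list(vars = uvars[-nu], tab = rowSums(tab))
    factors <- c(factors[!inv], list(newf))
  }
  post <- rep(1, 9)
  for (f in factors) {
    stopifnot(identical(f$vars, counselee))
    post <- post * f$tab
  }
  s <- sum(post)
  if (s <= 0) abort_combrisk("pedigree likelihood is zero under these parameters",
                             "combrisk_domain_error")
  post / s
}

# Greedy min-neighbourhood elimination order over all variables except the
# counselee; leaves first on trees.
elimination_order <- function(fa, mo, counselee, n) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  link <- function(i, j) {
    adj[[i]] <<- union(adj[[i]], j)
    adj[[j]] <<- union(adj[[j]], i)
  }
  for (i in seq_len(n)) {
    ps <- stats::na.omit(c(fa[i], mo[i]))
    for (p in ps) link(i, p)
    if (length(ps) == 2) link(ps[1], ps[2])  # moralisation
  }
  alive <- setdiff(seq_len(n), counselee)
  order_out <- integer(0)
  active <- rep(TRUE, n)
  while (length(alive) > 0) {
    sizes <- vapply(alive, function(v) sum(active[adj[[v]]]), numeric(1))
    v <- alive[which.min(sizes)]
    nb <- adj[[v]][active[adj[[v]]]]
    nb <- setdiff(nb, v)
    # connect neighbours (fill-in)
    if (length(nb) > 1) {
      for (a in nb) adj[[a]] <- union(adj[[a]], setdiff(nb, a))
    }
    active[v] <- FALSE
    alive <- setdiff(alive, v)
    order_out <- c(order_out, v)
  }
  order_out
}

fam_indices <- function(fam) {
  ids <- fam$member_id
  list(fa = match(fam$father_id, ids),
       mo = match(fam$mother_id, ids),
       counselee = which(fam$is_counselee == 1L))
}

#' Carrier-class posterior probabilities for each counselee
#'
#' Computes, for every family in `peds`, the exact posterior probability
#' that the counselee belongs to each carrier class (`none`, `brca1`,
#' `brca2`, `both`), by sum-product elimination (peeling) over the family's
#' joint genotype distribution: Hardy-Weinberg founder priors, Mendelian
#' transmission independently per gene, and phenotype/test emissions from
#' the penetrance tables. Unknown parents are treated as unrelated founders
#' with population genotype priors.
#'
#' @param peds Validated pedigree tibble (one or more families).
#' @param params [mendelian_params()].
#' @param validate Revalidate the table first (default TRUE).
#' @return A tibble with columns `family_id`, `p_none`, `p_brca1`,
#'   `p_brca2`, `p_both`; each row sums to 1.
#' @export
carrier_posteriors <- function(peds, params, validate = TRUE) {
  if (validate) peds <- validate_pedigrees(peds, a_max = params$a_max)
  prior9 <- hw_prior9(params$allele_freq_brca1, params$allele_freq_brca2)
  M9 <- marginal_transmission9(prior9)
  lik4 <- class_likelihoods(peds, params)
  emis9_all <- lik4[, STATE_CLASS_IDX, drop = FALSE]
  fids <- unique(peds$family_id)
  rows <- split(seq_len(nrow(peds)), factor(peds$family_id, levels = fids))
  out <- matrix(NA_real_, length(fids), 4)
  for (k in seq_along(fids)) {
    r <- rows[[k]]
    fam <- peds[r, ]
    ix <- fam_indices(fam)
    post9 <- peel_one(ix$fa, ix$mo, ix$counselee,
                      emis9_all[r, , drop = FALSE], prior9, M9)
    out[k, ] <- as.numeric(rowsum(post9, STATE_CLASS_IDX)[, 1])[
      sort(unique(STATE_CLASS_IDX))]
    # rowsum orders by group id 1..4 already
  }
  tibble::tibble(family_id = fids,
                 p_none = out[, 1], p_brca1 = out[, 2],
                 p_brca2 = out[, 3], p_both = out[, 4])
}

#' Brute-force carrier posteriors (test oracle)
#'
#' Exhaustive enumeration over the joint genotype configurations of all
#' family members. Reference implementation for [carrier_posteriors()];
#' limited to 7 members.
#'
#' @inheritParams carrier_posteriors
#' @return Same shape as [carrier_posteriors()].
#' @export
brute_force_posteriors <- function(peds, params, validate = TRUE) {
  if (validate) peds <- validate_pedigrees(peds, a_max = params$a_max)
  prior9 <- hw_prior9(params$allele_freq_brca1, params$allele_freq_brca2)
  M9 <- marginal_transmission9(prior9)
  lik4 <- class_likelihoods(peds, params)
  emis9_all <- lik4[, STATE_CLASS_IDX, drop = FALSE]
  fids <- unique(peds$family_id)
  rows <- split(seq_len(nrow(peds)), factor(peds$family_id, levels = fids))
  res <- matrix(NA_real_, length(fids), 4)
  for (k in seq_along(fids)) {
    r <- rows[[k]]
    fam <- peds[r, ]
    n <- nrow(fam)
    if (n > 7) abort_combrisk("brute force limited to 7 members", "combrisk_size_error")
    ix <- fam_indices(fam)
    states <- as.matrix(do.call(expand.grid, rep(list(1:9), n)))
    w <- rep(1, nrow(states))
    emis9 <- emis9_all[r, , drop = FALSE]
    for (i in seq_len(n)) {
      w <- w * emis9[i, ][states[, i]]
      if (is.na(ix$fa[i]) && is.na(ix$mo[i])) {
        w <- w * prior9[states[, i]]
      } else if (!is.na(ix$fa[i]) && !is.na(ix$mo[i])) {
        w <- w * transmission9[cbind(states[, i], states[, ix$fa[i]], states[, ix$mo[i]])]
      } else {
        p <- if (is.na(ix$fa[i])) ix$mo[i] else ix$fa[i]
        w <- w * M9[cbind(states[, i], states[, p])]
      }
    }
    post9 <- as.numeric(rowsum(w, states[, ix$counselee]))
    post9 <- post9 / sum(post9)
    res[k, ] <- as.numeric(rowsum(post9, STATE_CLASS_IDX)[, 1])
  }
  tibble::tibble(family_id = fids,
                 p_none = res[, 1], p_brca1 = res[, 2],
                 p_brca2 = res[, 3], p_both = res[, 4])
}

# ---- Crude future risk ------------------------------------------------------

# Discrete crude risk from vectorised hazard chains.
# h_bc: vector (length a_max) or matrix (n x a_max); h_d: vector.
crude_risk_chain <- function(a0, tau, h_bc, h_d) {
  n <- length(a0)
  if (tau == 0) return(rep(0, n))
  risk <- rep(0, n); S <- rep(1, n)
  mat <- is.matrix(h_bc)
  for (t in seq_len(tau)) {
    idx <- a0 + t
    hb <- if (mat) h_bc[cbind(seq_len(n), idx)] else h_bc[idx]
    hd <- h_d[idx]
    risk <- risk + S * hb
    S <- S * pmax(1 - hb - hd, 0)
  }
  risk
}

#' Genotype-specific crude future risk of breast cancer
#'
#' The probability that a woman unaffected through `age` develops breast
#' cancer within the next `tau` years, given carrier class, accounting for
#' death from other causes as a competing event. Computed by the discrete
#' recursion `sum_t h_bc(t) prod_{s<t} (1 - h_bc(s) - h_death(s))` over
#' `t = age+1, ..., age+tau`, where `h_bc` is the conditional annual
#' breast-cancer hazard `f(a) / (1 - F(a-1))`.
#'
#' @param age Baseline age(s), whole years (vectorised).
#' @param tau Projection horizon in years; `age + tau` must stay inside the
#'   penetrance table.
#' @param carrier_class One of `"none"`, `"brca1"`, `"brca2"`, `"both"`.
#' @param params [mendelian_params()].
#' @param penetrance Optional replacement penetrance table (e.g. a modified
#'   one); defaults to `params$penetrance`.
#' @param sex `"female"` (default) or `"male"`.
#' @return Risk(s) in `[0, 1]`, nondecreasing in `tau`.
#' @export
genotype_future_risk <- function(age, tau, carrier_class, params,
                                 penetrance = NULL, sex = "female") {
  pen <- penetrance %||% params$penetrance
  stopifnot(carrier_class %in% CARRIER_CLASSES, tau >= 0)
  if (any(age + tau > pen$a_max) || any(age < 0)) {
    abort_combrisk("age + tau outside the penetrance table", "combrisk_range_error")
  }
  tab <- if (sex == "female") "breast_female" else "breast_male"
  Fm <- pen$F[[tab]][, carrier_class]
  F_age <- ifelse(age >= 1, Fm[pmax(age, 1)], 0)
  F_age[age < 1] <- 0
  if (any(F_age >= 1 - 1e-12)) {
    abort_combrisk("cumulative penetrance is 1 at baseline: no survivors of this class",
                   "combrisk_degenerate_error")
  }
  h_bc <- pen$h[[tab]][, carrier_class]
  h_d <- params$mortality[, sex]
  crude_risk_chain(age, tau, h_bc, h_d)
}

#' Family-history based future risk of breast cancer
#'
#' The Mendelian model's future-risk output: the carrier-class posterior
#' for each counselee, mixed with the genotype-specific crude risks.
#'
#' @param peds Validated pedigree tibble.
#' @param params [mendelian_params()].
#' @param tau Projection horizon (years).
#' @param validate Revalidate pedigrees first.
#' @return A tibble with `family_id`, `tau`, and `risk`.
#' @export
brcapro_risk <- function(peds, params, tau, validate = TRUE) {
  post <- carrier_posteriors(peds, params, validate = validate)
  cz <- peds[peds$is_counselee == 1L, ]
  cz <- cz[match(post$family_id, cz$family_id), ]
  risks <- vapply(CARRIER_CLASSES, function(cl) {
    genotype_future_risk(cz$age_baseline, tau, cl, params)
  }, numeric(nrow(post)))
  if (is.null(dim(risks))) risks <- matrix(risks, nrow = 1)
  mix <- rowSums(as.matrix(post[, c("p_none", "p_brca1", "p_brca2", "p_both")]) * risks)
  tibble::tibble(family_id = post$family_id, tau = tau, risk = mix)
}
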
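---
title: "Combining Mendelian and relative-hazard breast cancer risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining Mendelian and relative-hazard breast cancer risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two families of breast cancer risk models are in wide clinical use. Mendelian
models translate a detailed family history of breast and ovarian cancer into
a posterior probability that the counselee carries a deleterious BRCA1/BRCA2
mutation, then project her future risk as a mixture of genotype-specific
penetrance curves. Regression-based relative-hazard models instead multiply a
population baseline hazard by exponentiated coefficients for
hormonal/reproductive risk factors, biopsy history, and a coarse summary of
family history. The two inputs are largely complementary, and `combrisk`
implements two ways of putting them together:

* **Penetrance modification** — the covariate relative hazard `RR(a)` from
  the regression model scales the *non-carrier* annual breast-cancer hazard
  inside the Mendelian future-risk calculation,
  `h0(a) -> min(1, h0(a) * F_cal(a) * RR(a))`, under a discrete
  proportional-hazards model. Carrier hazards are left untouched because the
  relative-hazard model is not recommended for known mutation carriers, and
  covariate effects on carriers are poorly characterised. The final risk is
  again the posterior-weighted mixture over carrier classes.
* **Stacked ensembles** — a meta-model trained on individual-level outcomes
  with the two base-model predictions as inputs: a logistic regression for
  the binary tau-year outcome, and a Fine-Gray proportional
  subdistribution-hazards model (death as the competing risk) for the
  time-to-event outcome. Both use `sqrt(p1)`, `sqrt(p2)` and their product
  as covariates; the square-root transform counters the strong right skew
  of risk predictions, and we transform first, then take the product (the
  alternative order is a documented design choice, not a fitted one).

A pedigree/cohort simulator generates data under the penetrance-modification
process so that every downstream module is testable without access to any
cohort data, and an IPCW-based evaluation suite scores predictions under
right censoring.

# The Mendelian engine

Genotypes are tracked per gene as copy numbers {0, 1, 2} (9 joint states),
and collapsed to the four carrier classes (none / BRCA1 / BRCA2 / both) only
where penetrance is evaluated. Founders receive Hardy–Weinberg priors;
transmission is Mendelian and independent across the two genes. The
counselee posterior is computed by exact sum–product variable elimination
(peeling) over the family graph, with a greedy smallest-neighbourhood
elimination order — leaves first on trees. Correctness, not speed, is the
contract, and a brute-force enumeration oracle (`brute_force_posteriors()`)
is part of the public API; the two agree to well below 1e-9 on hundreds of
random pedigrees in the test suite.

Emissions follow the discrete-time convention that "age a" phenotypes mean
status as of the end of year `a`: an affected member contributes `f(onset)`,
a known-unaffected member contributes `1 - F(age)` where `age` is the
current age for the living and the age at death for the deceased (so onsets
recorded after death are impossible by construction), and a missing status
contributes 1 — no information, never imputed as unaffected. Germline test
results enter through per-gene sensitivity/specificity factors (defaults 1).

Members must be first- or second-degree relatives of the counselee. Unknown
parents are treated as unrelated founders with population genotype priors.
This matters for the counselee's children, whose other parent is not a blood
relative and therefore cannot appear in the pedigree: the likelihood
marginalises each such co-parent as an independent Hardy–Weinberg founder,
and the simulator draws an independent founder spouse per child, so the
generator and the likelihood describe the same model. With several children
of one union this treats the union's parents as exchangeable founders rather
than a single shared spouse; given realistic allele frequencies the
difference is negligible, and making the two sides consistent is what the
calibration guarantees require.

## Crude risk

Future risk respects death from other causes as a competing event. We use
the standard discrete crude-risk recursion

```
risk(a0, tau) = sum_{t=a0+1}^{a0+tau} h_bc(t) * prod_{s=a0+1}^{t-1} (1 - h_bc(s) - h_d(s))
```

with `h_bc(t) = f(t) / (1 - F(t-1))` the conditional annual cancer hazard
and `h_d` the annual other-cause mortality. With constant `h_bc = h` and no
mortality this reduces to `1 - (1-h)^tau`, which the tests assert exactly.
We state this recursion as the package's definition of the crude option;
implementations that attach the competing decrement multiplicatively rather
than additively differ only at second order in the annual hazards.

# The relative-hazard model

The regression structure is fixed — main effects for age at menarche,
number of biopsies, age at first live birth and number of affected female
first-degree relatives; two age bands (default `<50` / `>=50`); an
(age band x biopsies) interaction and an (age at first birth x affected
relatives) interaction; atypical-hyperplasia multipliers applied when at
least one biopsy was taken — while all numbers are configuration. The
shipped default coefficient set is the published White-population values;
the default baseline hazard table is a synthetic SEER-like Weibull curve,
deliberately distinct from the Mendelian non-carrier table because the two
model families draw their baselines from different sources. `unknown`
biopsy/hyperplasia categories map to the neutral multiplier 1.

The attributable-risk calibration factor `F_cal(a)` scales the relative
hazards to be compatible with a population-average baseline; the default is
the published two-band `1 - AR` pair (0.5788 under age 50, 0.4761 above).
The penetrance-modification model uses `RR(a) * F_cal(a)`, so that a
counselee with a population-average covariate profile approximately
reproduces the unmodified baseline — without `F_cal`, every covariate
profile would sit above baseline and the combined model would not nest the
Mendelian model at the population average.

# The simulator

`simulate_cohort()` draws counselee-centred families (counselee, parents,
four grandparents, and sampled siblings, children and aunts/uncles —
everyone within two degrees), assigns birth years generation by generation
with Gaussian parent–child gaps (mean 27, sd 6, truncated so every parent is
at least 12 years older than each child, taking the younger of the two
parents as the reference), and death ages for non-counselees from a
truncated normal with mean 80 and sd 15. Genotypes descend by Mendelian
transmission from Hardy–Weinberg founders; baseline phenotypes are drawn
from the genotype-specific penetrance with onsets after the observation
window (death) recoded unaffected; counselees with breast cancer at baseline
are excluded. Five-year outcomes are then drawn from the
penetrance-modification distribution of the counselee's *true* genotype,
rescaled to condition on being unaffected at baseline, and are not subject
to censoring. Because the predictor integrates the same likelihood over the
genotype it cannot see, the generating model's predictions are calibrated by
construction — the headline property the acceptance checks measure. An
optional censoring mechanism exists only inside the metric tests, to
exercise the IPCW machinery; the generated 5-year outcome itself is never
censored.

Study-condition defaults were chosen once to emulate a family-history
enriched referral cohort and the reported simulation setting: Ashkenazi-like
allele frequencies (0.013 / 0.009), counselee baseline ages ~ N(47, 12)
truncated to [20, 75], sibling counts ~ capped Poisson(2), and covariate
category probabilities (menarche .15/.50/.35, biopsies .60/.25/.15,
hyperplasia .82/.08/.10 among the biopsied) set so that the event-weighted
mean of `F_cal * RR` is about 1.15. Under these conditions the two base
models under-predict (O/E around 1.15–1.30) while the combined model stays
calibrated, the qualitative pattern the combination approach is designed to
produce; the 5-year event rate is just under 2%. What passing these checks
shows is internal consistency at realistic magnitudes — the simulator knows
nothing about screening behaviour, secular incidence trends, measurement
error in family history, or covariate correlations, so performance on real
cohorts is a separate, empirical question.

Generation is fully vectorised under a single seeded stream: the same seed
and `n_families` reproduce the output byte for byte. A family's draw is not
invariant to `n_families`; we preferred a two-orders-of-magnitude speedup
(the acceptance design simulates 100,000 families in seconds) over
per-family substreams.

# Evaluation under censoring

For the tau-year binary outcome, subjects whose outcome is known — diagnosed
by `tau`, followed event-free to `tau`, or dead before `tau` — are weighted
by the inverse Kaplan–Meier censoring survival `1 / G(min(tau, T)-)`,
estimated from the censored subjects (optionally per stratum, matching
designs where follow-up differs by centre); subjects censored before `tau`
get weight zero. With no censoring every weight is 1 and each of the five
measures (O/E, AUC, Brier, logarithmic score, standardized net benefit at
the 1.67% chemoprevention threshold) collapses exactly to its textbook
formula — asserted to machine precision in the tests. Ties in the AUC count
one half. Wilson intervals in the decile calibration table use the weighted
count as the effective sample size. For the time-to-event outcome the
package provides the IPCW-truncated concordance (default truncation 10
years; perturbation interval from at least 500 unit-mean exponential
multipliers) and a competing-risks logarithmic score over predicted
(year, cause) distributions, which is strictly proper under non-informative
censoring.

`bootstrap_compare()` resamples counselees, re-estimates censoring weights
inside each replicate, and reports percentile CIs and pairwise win
proportions. "Better" means higher AUC/SNB, lower Brier/logarithmic score,
and O/E closer to 1 on the log scale (the O/E comparison rule is our
documented choice); ties are not wins; replicates with no cases are dropped
and counted.

# Importance weighting

When the ensembles are trained on one population and deployed on another,
training rows can be reweighted by the target/train covariate density ratio.
`fit_density_ratio()` implements least-squares importance fitting: a
nonnegative combination of Gaussian kernels centred on (up to 100) target
rows, coefficients solved in closed form from the ridge-regularised
least-squares system, with the bandwidth (median-heuristic multiples 1/4–4)
and ridge penalty (1e-3–10) chosen by 5-fold cross-validation of the
squared-error criterion and negative coefficients truncated to zero. Two
numerical points are deliberate: the cross-validation scores the *truncated*
solution, because the raw solution of an ill-conditioned system can fake a
low held-out objective through cancelling oscillations; and both grids use
half-octave/half-decade steps because the CV landscape is flat enough that
coarser grids occasionally select a visibly oversmoothed fit. The fitted
mean weight under matched distributions is close to, but not exactly, 1
(ridge shrinkage biases it downward by about 1% at n = 5000), which is why
`training_weights()` offers explicit renormalisation rather than silently
rescaling.

# Numerical choices and degenerate inputs

* Scaled hazards are clipped at 1 (they are probabilities); clipping warns.
* A pedigree whose phenotypes have zero likelihood under the parameters
  (e.g. contradictory perfect test results) raises an error rather than
  returning NaNs; so do cyclic parent links, onset ages outside the
  penetrance table, and baseline ages at which the cumulative penetrance has
  already reached 1.
* Collinear base predictions trigger a warning and aliased stacking terms
  are treated as zero at prediction time.
* The logistic ensemble refuses constant outcomes; the Fine-Gray ensemble
  refuses data without breast-cancer events and predictions beyond the
  observed training horizon.
* Fewer distinct predictions than calibration bins triggers a fallback to
  the achievable bin count, with a warning.

# Problem sizes

The test suite runs its end-to-end checks on a shared simulation of 90,000
families (~86,000 eligible counselees) and its oracle checks on hundreds of
small random pedigrees; the acceptance script simulates 100,000 families —
the design size — and trains the ensembles on the first half of the eligible
counselees. On a single CPU the script completes in about four minutes,
dominated by exact peeling at roughly 2 ms per family.

# Known limitations

* Two genes only; no polygenic component, interventions (mastectomy /
  oophorectomy), twins, or consanguinity loops; ovarian cancer enters the
  likelihood but is not a future-risk output.
* The peeling engine targets small within-two-degrees families; it is exact
  on any acyclic pedigree but makes no attempt at large-loop performance.
* All shipped parameter tables are synthetic fixtures with realistic
  magnitudes, not literature estimates; real analyses must supply published
  penetrance, mortality, coefficient and baseline-hazard tables through the
  configuration interfaces.
* The eligibility rule implemented for the relative-hazard model is the
  minimum-age rule only.
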
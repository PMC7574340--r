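---
title: "Small-area prevalence estimation with CAR spatial models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area prevalence estimation with CAR spatial models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carprev)
```

## The estimation problem

Near-census collections of a binary outcome (the motivating setting is
child developmental vulnerability, assessed for every child entering
school and aggregated to statistical regions of 30,000–130,000 people)
give per-region totals `N_r` and event counts `y_r`. The direct estimator
`y_r / N_r` has binomial standard error `sqrt(p(1-p)/N)`, so its percent
coefficient of variation `CV = sd/estimate × 100` explodes as `N_r`
shrinks, and regions under the reporting minimum (15 assessed) are
suppressed outright. The package fits a Bayesian spatial model that pools
information across neighbouring regions, yielding estimates whose CV is
smaller than the direct one — most markedly in the smallest regions — and
producing estimates even where the response or the covariate is missing.

## Model

The hierarchy is

* likelihood: `y_r ~ Binomial(N_r, p_r)`;
* link: `logit(p_r) = α + X_rᵀβ + u_r + v_r`, optionally plus a log
  offset `log(e_r)` for a relative-risk parameterization (off by default:
  with the offset enabled the linear predictor models log relative risk
  rather than logit prevalence, and the two interpretations should not be
  mixed);
* `v_r ~ N(0, τ_v²)` iid (pure overdispersion);
* `u_r` spatially structured. The ICAR conditional is
  `u_j | u_{-j} ~ N(Σ_i u_i w_ji / d_j, τ_u² / d_j)` with binary Queen
  first-order weights; the Leroux extension replaces `d_j` by
  `ρ d_j + (1 − ρ)`, scaling the conditional mean by `ρ`, and so
  interpolates between independent effects (`ρ = 0`) and ICAR (`ρ = 1`).

Model variants: `leroux` (default; structured effect with free `ρ`, plus
`v`), `bym` (ICAR + iid), `icar_only`, `iid_only`. The BYM decomposition
is also what the Gaussian smoother used for covariate imputation fits.

### Priors and hyperparameters

| parameter | prior | default | rationale |
|---|---|---|---|
| `1/τ_u²` | Gamma(shape `α_u`, rate `β_u`) | (1, 0.5) | weakly informative; conjugate with the CAR quadratic form |
| `1/τ_v²` | Gamma(`α_v`, `β_v`) | (1, 0.01) | flatter, so the iid term can absorb overdispersion |
| `α`, `β` | N(0, `beta_prior_sd`²) | sd 10 | weak on the standardized-covariate scale |
| `ρ` | Uniform(0, 1) | — | no stated prior in the model family's common usage dominates; uniform is the conventional default |

The gamma priors are placed on the *precisions* (equivalently,
inverse-gamma on the variances). The variance–precision wording is
ambiguous in parts of the literature this model family comes from; the
precision-side gamma is the choice that makes the Gibbs step conjugate
and matches the usual "normal–inverse-gamma" phrasing.

The covariate is standardized by default (sample sd, n−1 denominator);
only the affine transform matters downstream, and the returned
center/scale place out-of-sample scores on the fitted scale. Whether a
disadvantage index should enter raw, standardized, or as ranks is a
sensitivity question; standardization is the default because it
stabilizes the random-walk updates and makes the `N(0, 10²)` coefficient
prior meaningfully weak.

## Sampler

A Metropolis-within-Gibbs scheme, implemented in C++:

* component-wise adaptive random-walk Metropolis for `α` and `β`;
* single-site random-walk Metropolis for each `u_r` (target = region
  likelihood × Leroux full conditional) and each `v_r`;
* conjugate inverse-gamma Gibbs draws for `τ_u²` (shape `α_u + n*/2`,
  rate `β_u + Q(u)/2`, where `Q` is the CAR quadratic form and `n*` the
  effective rank: `n` for Leroux with `ρ < 1`, `n` minus the number of
  connected components for ICAR) and `τ_v²`;
* Metropolis on `logit(ρ)` with the exact Leroux log determinant computed
  from the pre-computed eigenvalues of the graph Laplacian;
* an interweaving shift move `(α, u) → (α + δ, u − δ)` (and likewise for
  `v`). The likelihood only identifies `α + mean(u)`, so single-site
  updates alone traverse this ridge very slowly and the intercept's
  posterior spread would be understated; the shift move costs O(n) and
  leaves the likelihood invariant.

Numerical and identifiability choices:

* ICAR impropriety is handled by re-centring `u` to sum to zero each
  sweep, with the shift absorbed into the intercept (linear predictor
  unchanged).
* Proposal step sizes adapt every 50 iterations during burn-in only,
  multiplying by 1.15 when block acceptance exceeds 50% and dividing when
  it falls under 30%; they are frozen at the end of burn-in so the
  retained chain satisfies detailed balance.
* Regions with `NA` responses or `N = 0` contribute no likelihood term;
  their random effects are drawn from the prior conditionals so the graph
  stays intact.
* The binomial log likelihood uses a stable `log(1 + e^η)` evaluation.
* Defaults are 50,000 iterations, 10,000 burn-in, thinning 10 (run
  lengths are not dictated by the model; these are conservative choices
  for a production run — the examples and tests use shorter schedules,
  stated below). One chain with full seed control; identical seed and
  inputs give bit-identical draws.

## Geography

Queen contiguity ("share at least one boundary point", the chess-queen
analogy) is the default neighbourhood; a Rook option (shared boundary
segments of positive length only) exists for sensitivity checks, because
whether corner-only contact should count is a genuine convention choice
polygon sources do not settle. Contact is detected by segment–segment
proximity within `1e-9` coordinate units to absorb floating-point slivers
in polygonised boundaries. Regions with no neighbours cannot carry an
ICAR effect and are removed by `find_and_remove_isolated()` before
modelling. Region order is input order; a single ordering indexes all
matrices and vectors downstream.

## Missing data

Two administrative mechanisms, treated as ignorable:

* **Missing response** (suppression under the reporting minimum): the
  model is fitted with the region's likelihood term absent, and the
  reported estimate is the plug-in `p_r(β̂, 0, 0)` — the inverse logit of
  the fixed effects only, averaged over the posterior. The default uses
  the full posterior of `β` rather than a point estimate (a
  `point_estimate` switch matches the literal plug-in). The interval
  therefore reflects fixed-effect uncertainty only, not random-effect
  spread; that matches the plug-in definition, and a predictive interval
  adding `N(0, τ_u² + τ_v²)` draws can be formed from the samples if
  wanted.
* **Missing covariate** (regions too sparsely populated to compute an
  index): a Gaussian BYM smoother (intercept + ICAR + iid, all-conjugate
  Gibbs, error precision `~ Gamma(1, 0.01)`, fitted on the standardized
  scale) is fitted to the observed scores and its posterior-mean surface
  fills the gaps. The posterior mean is plugged in without propagating
  imputation uncertainty — the plug-in convention for this pipeline —
  with the smoother's posterior sd available for sensitivity analysis.

The canonical pipeline (`sae_pipeline()`) applies suppression, imputes
covariates, fits, and tags every region's estimate with provenance
(`fitted`, `plug-in`, `imputed-covariate`), so no region is left without
an estimate. Regions lacking a direct estimate are excluded from the
model-vs-direct comparison metrics and listed explicitly.

## Diagnostics

`cv_difference()` (direct minus model CV, percentage points) and
`relative_bias()` (`(p̂ᵉ − p̂ᵒ)/p̂ᵉ × 100`; positive = direct
under-estimates) compare the two estimators per region;
`quantile_bins()` cuts any metric at its 20/40/60/80 percentiles (linear
interpolation between order statistics; ties on a cutpoint go to the
lower bin, stated for bit-exact reproducibility) into the five classes a
choropleth map would use. `random_effect_normality()` scores the
normal q–q straightness of posterior-mean effects, and
`sensitivity_refit()` reports the maximum absolute change in posterior
prevalence means under alternative hyperpriors.

## The synthetic-study generator

`generate_study()` realizes the model's own data-generating process on a
Queen-contiguity lattice (truncatable to any region count, optionally
padded with isolated regions):

* **Assessed counts** `N_r`: lognormal with `meanlog = 6.53`,
  `sdlog = 0.71`, solved analytically from the target profile of a
  near-census early-development collection (mean ≈ 878 children per
  region, interquartile range ≈ 679), truncated at 4441 by resampling and
  floored. Near-empty regions (the source of suppression) are injected
  explicitly (`n_small`, Poisson mean 5 capped at 14) rather than by
  stretching the lognormal tail.
* **Covariate**: each region averages its own and its neighbours' iid
  normal draws, then is scaled to an index-like mean 1000 / sd 80
  (≈ 600–1200 span) — spatially autocorrelated like a real disadvantage
  index without importing any data. The generator treats the covariate as
  purely area-level, as the model does.
* **Effects**: `u` drawn exactly from the Leroux prior (Cholesky of the
  precision; at `ρ = 1`, from the constrained ICAR prior via the
  Laplacian eigendecomposition with the null space removed), `v` iid.
  Defaults `β = (−2.2, −0.5)`, `τ_u² = 0.2`, `τ_v² = 0.05`, `ρ = 0.9`
  give prevalences in the 7–10% band of the motivating collection.
* **Counts**: `y_r ~ Binomial(N_r, p_r)`, or aggregated unit-level
  Bernoulli draws when per-child records are wanted.
* **Classification**: `assign_categories()` freezes cut-offs from a
  reference cohort (10%/25% rank order statistics, closed lower rule) so
  later cohorts are classified against fixed thresholds.
* **Missingness**: `inject_missingness()` applies the reporting minimum
  to responses and strips the covariate from a chosen set of regions
  (default: the two smallest-N unsuppressed ones, reproducing the
  2 + 2 pattern of the motivating data).

All truth (effects, prevalences, parameters) is stored losslessly, and
the same seed regenerates every field bit-identically.

### What passing tests do and do not show

The generator emulates the *statistical* structure the model assumes:
binomial sampling, area-level covariate, CAR spatial correlation, skewed
population sizes, administrative missingness. It does not emulate
model misspecification present in real collections — non-binomial
within-region clustering, covariate measurement error, informative
missingness, irregular adjacency structures of real boundary files, or
cross-domain correlation when several outcomes are assessed on the same
children (domains are fitted independently here). Recovery and shrinkage
results on synthetic studies therefore validate the implementation and
the method's behaviour *under its own assumptions*, not its adequacy for
any particular real dataset.

## Problem sizes and schedules used in the tests

Unit tests run on 3×3 to 10×10 lattices with chains of 1,500–4,000
iterations; the statistical acceptance checks use 20 replicates of a
15×15 grid at 12,000 iterations (fixed-effect interval coverage ≥ 80%),
a single 335-region study for shrinkage and the 2 + 2 missing-data round
trip, 10 paired hold-out seeds for imputation, and 10⁵ Gibbs draws for
the conjugate-step moment check (on a 100-region path graph, where the
inverse-gamma shape ≈ 50.5 has finite fourth moments and a 1% moment
tolerance is statistically meaningful). These sizes are the package's
own calibration choices: large enough for the properties to be sharp,
small enough to run routinely.

## Known limitations

* Single-outcome models only; no multivariate CAR for correlated domains.
* No INLA-style deterministic approximation; inference is MCMC.
* Imputation and plug-in uncertainty are not propagated into the main
  model (by design, matching the plug-in convention); multiple-imputation
  propagation is a possible extension.
* Planar coordinates are assumed for polygon input; no projection
  handling.
* `ρ` is weakly identified on modest lattices (its posterior is wide and
  its point estimate typically below a high generating value); the
  intercept's posterior correctly widens with the level-identifiability
  ridge, but coverage for it sits near — not comfortably above — nominal
  at a few hundred regions.
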
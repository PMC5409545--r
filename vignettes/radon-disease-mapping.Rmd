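---
title: "Methods: lognormal kriging and BYM disease mapping in radonmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lognormal kriging and BYM disease mapping in radonmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonmap)
```

## The problem

Ecological (geographical-correlation) studies of indoor radon relate a
region-level exposure — the mean indoor radon concentration in Bq/m³ — to
region-level cancer incidence. Three methodological pieces are needed and
`radonmap` implements all of them as one tested pipeline:

1. **Exposure surface.** Radon is measured at scattered survey points and
   is strongly right-skewed: most dwellings are low, a few are extreme.
   Interpolation is therefore done on the log scale (ordinary *lognormal
   kriging*), followed by a bias-corrected back-transform, and the
   interpolated grid is averaged within each administrative region.
2. **Outcome standardization.** Observed cancer counts per region are
   compared with counts expected from the region's sex and 5-year-age
   structure (indirect standardization), giving a standardized incidence
   ratio SIR$_i = O_i / E_i$.
3. **Risk regression.** A Bayesian hierarchical Poisson model with
   spatially structured and unstructured random effects estimates the
   relative risk per 10 Bq/m³ with 95% credible intervals.

Because national survey and cancer-registry microdata are not
distributable, the package ships a synthetic-data generator that emulates
their statistical structure, and every downstream method is validated
against it.

## The exposure model

The latent log-radon field is a stationary Gaussian random field with
semivariogram $\gamma(h)$ (spherical, exponential or gaussian family;
nugget $c_0$, partial sill $c$, range $a$). Field simulation uses the
implied covariance $C(h) = (c_0 + c) - \gamma(h)$ and a dense Cholesky
factorization; grids are limited to 10,000 cells, which covers desk-scale
experiments comfortably (the package's own experiments use 50 × 50 cells at
1 km spacing). Larger national grids are out of scope.

`calibrate_field_params()` chooses the total log-scale variance $s^2$ so
that the marginal lognormal distribution has a requested skewness
(default 7.84, solving $(e^{s^2}+2)\sqrt{e^{s^2}-1} = \text{skew}$), and
sets the log-mean to the log of a requested geometric mean (default
49 Bq/m³). The variance is partitioned into three components:

* iid measurement noise (default sd 0.45 on the log scale),
* a micro-scale nugget, and
* a spatially structured component (default 34% of the total variance,
  exponential with range parameter 3 km, i.e. a practical range of ~9 km).

The large unstructured share reflects what indoor-radon surveys show:
building construction, ventilation and floor level dominate
dwelling-to-dwelling variation, while the geological signal is a
shorter-range, smaller-amplitude component. With these defaults the
domain-average geometric mean is stable across realizations (verified as a
Monte-Carlo check over ten seeds), while regional means still spread enough
to identify a regression slope.

### Kriging

The empirical semivariogram is the classical Matheron estimator on
equal-width lag bins up to half the domain diagonal; duplicate locations
are tallied at zero lag only. Model fitting minimizes the Cressie-weighted
least-squares criterion $\sum_k N_k(\hat\gamma_k/\gamma_k - 1)^2$ with box
constraints, multiple data-driven starts, and a derivative-free polish; the
default family is spherical with an exponential fallback.

Prediction solves the ordinary-kriging system in semivariogram form with a
moving neighborhood (nearest 16 points within three practical ranges; a
cell with an empty neighborhood falls back to the global mean and is
flagged). Coincident points are averaged on the log scale before solving —
consistent with annual-average semantics and guaranteeing a nonsingular
system. The back-transform is the standard unbiased form for ordinary
lognormal kriging,
$$\hat z = \exp(\hat y + \sigma^2_{OK}/2 - \mu_L),$$
where $\mu_L$ is the Lagrange multiplier. Under the multivariate lognormal
model this is exactly unbiased for $E[Z]$ (the naive $\exp(\hat y)$ is not,
and the test suite quantifies the contrast). Regional exposure is the
unweighted arithmetic mean of back-transformed cell values, which equals
the area-weighted mean on an equal-area grid.

## Standardization

Reference rates default to *internal* standardization: pooled national
rates $r(s,a) = \sum_i O(i,s,a) / \sum_i P(i,s,a)$, which forces
$\sum_i O_i = \sum_i E_i$ (a closure identity the tests check to 1e-9).
External rates can be supplied instead. The population denominator is a
single census-style snapshot, so the period length is absorbed into the
rates — the resulting SIR is internally consistent even though it is not a
true rate. Sex-specific analyses filter strata before pooling, so strata
are never mixed across sexes; child/adolescent analyses keep the 5-year
groups entirely below the age cut (e.g. 0–4 … 15–19 for a cut at 19).

## The disease-mapping model

For regions $i = 1,\dots,n$ with observed counts $O_i$ and expected counts
$E_i$:

$$O_i \sim \text{Poisson}(E_i e^{\eta_i}), \qquad
\eta_i = \alpha + x_i^\top\beta + u_i + v_i$$

* $x_i$ contains radon/10 (so $e^\beta$ is the RR per 10 Bq/m³); the
  adjusted model adds the centered sex-specific smoking rate and four
  indicators for deprivation quintiles 2–5 (rank-based quintiles, ties by
  first occurrence; 234 regions split 47/47/47/47/46).
* $u$ is the Besag intrinsic CAR effect with pairwise-difference density
  $\frac{n-1}{2}\log\tau_u - \frac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2$,
  identified by a sum-to-zero constraint. Adjacency is "shares a grid-cell
  edge" (queen vs rook is immaterial for grown cell partitions).
* $v_i \sim N(0, 1/\tau_v)$ is unstructured heterogeneity. Using the full
  convolution ($u + v$) is the standard disease-mapping reading of a
  Besag-type model with extra-Poisson variation; `include_v = FALSE`
  reduces it to a pure CAR model.
* Priors: coefficients $N(0, 10^6)$; precisions
  $\tau_u, \tau_v \sim \text{Gamma}(0.5, 0.0005)$, the WinBUGS-era
  weakly-informative convention, both exposed in `car_priors()`.

Sexes are fitted as separate models rather than interacted.

### Sampler

`mcmc_run()` is an adaptive Metropolis-within-Gibbs sampler:

* random-walk Metropolis for $\alpha$ and each $\beta_j$;
* single-site Metropolis for $u$ and $v$. The $u$-sites are updated in
  graph-color classes — within a class no two sites are neighbors, so the
  class updates are conditionally independent and fully vectorized. The
  $v$-sites are conditionally independent by construction and are updated
  as one vector;
* conjugate Gibbs draws
  $\tau_u \sim \text{Gamma}(a + (n-1)/2,\; b + \tfrac12\sum_{i\sim j}(u_i-u_j)^2)$
  and $\tau_v \sim \text{Gamma}(a + n/2,\; b + \tfrac12\sum v_i^2)$;
* after each sweep $u$ is recentred to sum to zero with the mean absorbed
  into $\alpha$, leaving the linear predictor unchanged (the identified
  parameterization);
* proposal scales adapt by Robbins–Monro ($t^{-0.6}$ decay) toward a 0.44
  acceptance rate; rates outside [0.1, 0.6] raise a warning, not an error.

Defaults mirror common practice: 5 parallel chains × 20,000 iterations,
burn-in 5,000, thinning 5 ("keep every fifth"). Chains start over-dispersed
via chain-indexed offsets on $\alpha$, $\beta$ and the precisions, and each
chain draws its RNG stream deterministically from the run seed, so a fit is
exactly reproducible. Convergence is assessed by the Gelman–Rubin
statistic $\hat R = \sqrt{(\frac{n-1}{n}W + \frac{B}{n})/W}$; posterior
summaries report the mean, median and equal-tailed 2.5/97.5% quantiles
(linear interpolation) on both the log-RR and RR scales, with RR quantiles
equal to the exponential of the log-scale quantiles.

## The synthetic generator and what passing tests mean

`simulate_strata_and_counts()` generates counts from *exactly* the model
above: region populations lognormal (median ≈ 120,000, clamped to a
plausible administrative range), split by sex and a built-in national-style
age structure; lung-like (steeply age-rising) or NHL-like (flat-low)
reference rates; $u$ drawn from the ICAR prior by eigendecomposition of
the graph Laplacian on its proper $(n-1)$-dimensional subspace (the prior
is improper, so generation needs the explicit sum-to-zero constraint); $v$
iid normal. Deprivation scores are standard normal; smoking rates uniform
in plausible sex-specific ranges (males 31.9–62.4%, females 0.4–12.5%);
true region radon either lognormal around 57 Bq/m³ or computed from a
simulated field as the cell mean of $\exp(\text{field})$.

The default true relative risk is 1.07 per 10 Bq/m³ with
$\sigma_u = \sigma_v = 0.1$ — a realistic ecological effect size and a
moderate amount of residual spatial structure. The recovery experiments
(200 regions, NHL-like expected counts, crude model, 5 chains × 4,000
iterations with burn-in 1,000 and thinning 5, 20 replicates per scenario)
check that the 95% CrI covers the truth at least 80% of the time at RR
1.07, 1.01 and 1.00, that the median log-RR bias is below 0.01, and that
$\hat R < 1.1$ for all reported coefficients. The reduced iteration count
relative to the 5 × 20,000 default was chosen as the smallest schedule at
which those convergence criteria hold comfortably.

What the generator does **not** emulate: the temporal design of a
multi-wave survey (no seasonal correction, no device effects), thoron,
preferential sampling of dwellings, realistic national geography, and
migration between regions. Passing tests therefore demonstrate
correctness of the estimators under their own assumptions — not that those
assumptions hold in any particular country's data.

Two deliberate structural facts about the end-to-end experiment are worth
stating. First, when counts are generated from the *true* region radon but
the model is fitted with the *kriged* exposure, the smoothing acts like a
Berkson-type error, so the slope remains approximately unbiased; the
parameter-recovery experiments use the true exposure to separate sampler
correctness from exposure-estimation error, and the end-to-end run
exercises the full path. Second, with internal standardization the crude
model's intercept is near zero by construction, which makes the reported
RR directly comparable across crude and adjusted fits.

## Numerical choices and degenerate inputs

* Variogram fits refuse fewer than three nonempty bins; a flat empirical
  variogram yields a pure-nugget model.
* The kriging solver clamps kriging variances in $[-10^{-9}, 0)$ to zero
  and errors on still-singular systems after duplicate averaging.
* The back-transform guards against overflow (exponent > 700) and
  non-finite inputs.
* `log_posterior()` returns $-\infty$ for non-finite linear predictors
  rather than raising.
* Quintile ties are broken by first occurrence; a covariate constant
  across regions is reported as rank-deficient rather than silently
  dropped.
* `summarize_posterior()` refuses fewer than 100 pooled draws;
  `gelman_rubin()` refuses degenerate (zero-variance) chains.
* All file formats are plain text (CSV, ESRI ASCII, edge list, JSON,
  YAML); identical configuration and seed reproduce artifacts
  byte-identically.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config(seed = 1)
cfg$grid <- list(nx = 30, ny = 30, dx = 1, dy = 1, x0 = 0, y0 = 0)
cfg$survey$n_points <- 1200
cfg$regions$n_regions <- 100
cfg$analysis$sexes <- "female"
cfg$mcmc <- list(n_chains = 5, n_iter = 4000, burn_in = 1000, thin = 5)
res <- run_end_to_end(cfg, outdir = "radon_demo")
res$report[, c("sex", "model", "rr_text", "rhat")]
```

## Known limitations

* Dense-Cholesky field simulation caps grids at 10,000 cells.
* No anisotropy, universal kriging, co-kriging or declustering.
* No DIC/WAIC model comparison, spatio-temporal structure or
  zero-inflation in the disease model.
* SIRs carry no standalone confidence intervals — uncertainty is handled
  by the Bayesian model.
* The sampler is single-machine and sequential across chains (determinism
  over parallel speed).
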
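# radonmap

Ecological spatial epidemiology of indoor radon: **lognormal kriging** of
point radon measurements, **standardized incidence ratios** by indirect
standardization, and **Bayesian disease mapping** with a Besag-CAR +
heterogeneity (BYM) Poisson model estimating the relative risk of cancer
per 10 Bq/m³ of radon.

The package is aimed at spatial epidemiologists and biostatisticians who
want a fully reproducible, dependency-light implementation of this classic
analysis chain — including a synthetic-data generator that emulates a
national radon survey and a cancer registry, because the real microdata
behind such studies are typically not distributable.

## The methods

**Exposure.** Indoor radon is strongly right-skewed, so interpolation is
done on the log scale. Ordinary kriging solves

```
[ Γ  1 ] [ w ]   [ γ₀ ]
[ 1′ 0 ] [ μ ] = [ 1  ]        ŷ = Σ wᵢ yᵢ ,   σ²OK = Σ wᵢ γ(hᵢ₀) + μ
```

and the unbiased lognormal back-transform is
`ẑ = exp(ŷ + σ²OK/2 − μ)`. The kriged grid is averaged within each
administrative region.

**Standardization.** With internal reference rates
`r(s,a) = Σᵢ O(i,s,a) / Σᵢ P(i,s,a)` over sex × 5-year age strata, expected
counts are `Eᵢ = Σ P(i,s,a)·r(s,a)` and `SIRᵢ = Oᵢ/Eᵢ`.

**Risk model.** `Oᵢ ~ Poisson(Eᵢ·exp(α + xᵢ′β + uᵢ + vᵢ))` where the radon
covariate is concentration/10 (so `exp(β)` is the RR per 10 Bq/m³), `u` is
a Besag intrinsic CAR effect on the region adjacency graph (sum-to-zero),
and `v` is iid normal heterogeneity. Fitting is adaptive
Metropolis-within-Gibbs (5 chains × 20,000 iterations by default, burn-in
5,000, thinning 5) with Gelman–Rubin convergence diagnostics and 95%
equal-tailed credible intervals. The adjusted model adds the centered
sex-specific smoking rate and deprivation-quintile indicators.

## Worked example

```r
library(radonmap)

cfg <- default_config(seed = 1)                      # truth: RR 1.07 / 10 Bq/m3
cfg$grid    <- list(nx = 30, ny = 30, dx = 1, dy = 1, x0 = 0, y0 = 0)
cfg$survey$n_points   <- 1200
cfg$regions$n_regions <- 100
cfg$analysis$sexes    <- "female"
cfg$mcmc <- list(n_chains = 5, n_iter = 4000, burn_in = 1000, thin = 5)

res <- run_end_to_end(cfg, outdir = "radon_demo")
res$report[, c("sex", "model", "rr_text", "rhat")]
#>      sex    model           rr_text     rhat
#> 1 female    crude 1.06 (1.04, 1.08) 1.047203
#> 2 female adjusted 1.06 (1.04, 1.08) 1.079835
```

The pipeline simulated a skewed log-radon field, sampled 1,200 survey
points, fitted a spherical variogram, kriged and back-transformed a
30 × 30 km grid, aggregated it to 100 regions, generated registry-like
counts at a true relative risk of 1.07 per 10 Bq/m³, and recovered
`1.06 (1.04, 1.08)` from the crude fit — the truth sits inside the credible
interval, and `R-hat` near 1 indicates converged chains. `radon_demo/`
contains every intermediate artifact as plain text (survey CSV, ESRI ASCII
grids, adjacency edge list, SIR tables, summaries, `report.txt`).

A thin CLI wrapper with `simulate | krige | sir | fit | report | run-all`
subcommands is installed at
`system.file("cli", "radonmap.R", package = "radonmap")`.

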
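# Synthetic region covariates, stratified populations, reference incidence
# rates, and Poisson cancer counts generated from the same log-linear
# spatial model the inference module fits.

AGE_GROUPS <- c("0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34",
                "35-39", "40-44", "45-49", "50-54", "55-59", "60-64",
                "65-69", "70-74", "75-79", "80+")

# Approximate national age structure (proportions by 5-year group, both
# sexes), an ageing-population shape with a thin top.
AGE_PROPS <- c(0.048, 0.052, 0.060, 0.068, 0.068, 0.072, 0.080, 0.086,
               0.088, 0.084, 0.074, 0.058, 0.048, 0.042, 0.034, 0.022,
               0.016)
AGE_PROPS <- AGE_PROPS / sum(AGE_PROPS)

age_group_bounds <- function(age_group) {
  lower <- as.numeric(sub("[-+].*$", "", age_group))
  upper <- ifelse(grepl("\\+$", age_group), Inf,
                  as.numeric(sub("^.*-", "", age_group)))
  cbind(lower = lower, upper = upper)
}

#' Built-in reference incidence rates by sex and age group
#'
#' Two schedules are provided: `"lung"` rises steeply with age and is much
#' higher in males (a lung-cancer-like schedule); `"nhl"` is low and nearly
#' flat in age (a non-Hodgkin-lymphoma-like schedule). Rates are cases per
#' person over the accrual period (the single-snapshot population is the
#' denominator, so the period length is absorbed into the rate).
#'
#' @param kind `"lung"` or `"nhl"`.
#' @return a data.frame with columns `sex`, `age_group`, `rate`.
#' @export
default_reference_rates <- function(kind = c("lung", "nhl")) {
  kind <- match.arg(kind)
  k <- length(AGE_GROUPS)
  idx <- seq_len(k)
  if (kind == "lung") {
    # negligible below ~35, roughly exponential rise thereafter
    base <- ifelse(idx < 8, 1e-6 * idx, 2e-5 * exp(0.55 * (idx - 8)))
    male <- base * 2.2
    female <- base * 0.75
  } else {
    # flat-low with a mild rise in late adulthood
    base <- 6e-5 + 4e-6 * idx + ifelse(idx > 12, 2e-5 * (idx - 12), 0)
    male <- base * 1.15
    female <- base * 0.85
  }
  data.frame(sex = rep(c("male", "female"), each = k),
             age_group = rep(AGE_GROUPS, 2),
             rate = c(male, female))
}

#' Ground-truth parameters for synthetic count generation
#'
#' Stored alongside generated data so that parameter-recovery experiments
#' can compare estimates with the values actually used.
#'
#' @param alpha log baseline relative risk (default 0).
#' @param beta_radon log relative risk per 10 Bq/m3 (default `log(1.07)`,
#'   a realistic ecological-study effect size).
#' @param beta_smoking log RR per percentage point of (centered) smoking
#'   rate (default 0).
#' @param beta_deprivation log RR per unit deprivation z-score (default 0).
#' @param sigma_u marginal scale of the spatially structured (ICAR) region
#'   effect (default 0.1).
#' @param sigma_v sd of the unstructured region effect (default 0.1).
#' @param seed integer seed recorded with the truth.
#' @return an object of class `truth_record`.
#' @export
truth_record <- function(alpha = 0, beta_radon = log(1.07),
                         beta_smoking = 0, beta_deprivation = 0,
                         sigma_u = 0.1, sigma_v = 0.1, seed = 1L) {
  vals <- c(alpha, beta_radon, beta_smoking, beta_deprivation,
            sigma_u, sigma_v)
  stopifnot(all(is.finite(vals)), sigma_u >= 0, sigma_v >= 0)
  structure(list(alpha = alpha, beta_radon = beta_radon,
                 beta_smoking = beta_smoking,
                 beta_deprivation = beta_deprivation,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 seed = as.integer(seed)),
            class = "truth_record")
}

#' Simulate region-level covariates
#'
#' Deprivation z-scores are standard normal; smoking rates are uniform
#' within the plausible sex-specific ranges for an East-Asian population
#' (males roughly 32--62%, females 0.4--12.5%); the true region-mean radon
#' is lognormal around a national median of 57 Bq/m3 unless supplied.
#'
#' @param n_regions number of regions.
#' @param seed integer seed.
#' @param radon_true optional vector of true region radon means (Bq/m3);
#'   if `NULL`, drawn lognormal(`log(57)`, `radon_sdlog`).
#' @param radon_sdlog log-scale sd of the drawn radon means (default 0.45).
#' @return a data.frame with `region`, `deprivation`, `smoking_male`,
#'   `smoking_female`, `radon_true`.
#' @export
simulate_region_covariates <- function(n_regions, seed = 1L,
                                       radon_true = NULL,
                                       radon_sdlog = 0.45) {
  set.seed(derive_seed(seed, 3000))
  if (is.null(radon_true)) {
    radon_true <- exp(stats::rnorm(n_regions, log(57), radon_sdlog))
  }
  stopifnot(length(radon_true) == n_regions, all(radon_true > 0))
  data.frame(region = seq_len(n_regions),
             deprivation = stats::rnorm(n_regions),
             smoking_male = stats::runif(n_regions, 31.9, 62.4),
             smoking_female = stats::runif(n_regions, 0.4, 12.5),
             radon_true = radon_true)
}

#' True region-mean radon from a simulated field
#'
#' Arithmetic mean of `exp(field)` over the cells of each region: the
#' ground-truth counterpart of the kriged-and-aggregated estimate.
#'
#' @param field per-cell log-radon values.
#' @param regions a `region_map`.
#' @return numeric vector of region means (Bq/m3), in region-id order.
#' @export
region_true_radon <- function(field, regions) {
  stopifnot(inherits(regions, "region_map"),
            length(field) == n_cells(regions$grid))
  counts <- region_sizes(regions)
  as.numeric(rowsum(exp(field), regions$membership)) / counts
}

#' Draw a spatially structured region effect from the ICAR prior
#'
#' The intrinsic CAR prior is improper, so a draw is generated on its proper
#' (n-1)-dimensional subspace: eigendecompose the graph Laplacian `Q = D - A`,
#' draw independent normals with variance `sigma_u^2 / lambda_k` on the
#' eigenvectors with positive eigenvalue, and enforce the sum-to-zero
#' constraint exactly.
#'
#' @param adjacency two-column matrix of unordered region pairs.
#' @param n_regions number of regions (adjacency graph must be connected).
#' @param sigma_u scale (`1/sqrt(tau_u)`); 0 returns the zero vector.
#' @return numeric vector `u` with `sum(u) == 0` (to 1e-10).
#' @export
icar_sample <- function(adjacency, n_regions, sigma_u) {
  stopifnot(sigma_u >= 0)
  if (sigma_u == 0 || n_regions == 1) return(numeric(n_regions))
  if (!adjacency_connected(adjacency, n_regions))
    stop("ICAR sampling requires a connected adjacency graph", call. = FALSE)
  Q <- matrix(0, n_regions, n_regions)
  for (r in seq_len(nrow(adjacency))) {
    i <- adjacency[r, 1]; j <- adjacency[r, 2]
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
    Q[i, i] <- Q[i, i] + 1
    Q[j, j] <- Q[j, j] + 1
  }
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  z <- stats::rnorm(sum(pos))
  u <- as.numeric(e$vectors[, pos, drop = FALSE] %*%
                    (z * sigma_u / sqrt(e$values[pos])))
  u - mean(u)
}

#' Simulate stratified populations and Poisson cancer counts
#'
#' Populations: region totals lognormal (median about 120,000, matching the
#' wide spread of real administrative regions), split roughly evenly by sex
#' and by the built-in national age structure. Counts: with `E(r,s,a) =
#' pop(r,s,a) * rate(s,a)`, observed cases per stratum are
#' `Poisson(E * theta_r(s))` where
#' `log theta_r(s) = alpha + beta_radon * radon_r / 10 +
#'  beta_smoking * (smoking_{r,s} - mean) + beta_deprivation * z_r + u_r + v_r`,
#' with `u` an ICAR draw (scale `sigma_u`, sum-to-zero) and `v` iid
#' `N(0, sigma_v^2)` -- the same log-linear model the inference module fits.
#'
#' @param regions a `region_map` (source of the CAR adjacency).
#' @param covariates data.frame from [simulate_region_covariates()].
#' @param truth a [truth_record()].
#' @param reference_rates data.frame from [default_reference_rates()] (or
#'   same shape).
#' @param seed integer seed.
#' @param pop_meanlog,pop_sdlog lognormal parameters of region totals.
#' @param populations optional data.frame (`region`, `sex`, `age_group`,
#'   `population`) fixing the population structure instead of drawing it
#'   (useful for conditioning replicate count draws on one population).
#' @return a data.frame (class `strata_table`) with columns `region`, `sex`,
#'   `age_group`, `population`, `observed`; attributes `u`, `v`, `theta`
#'   (per region x sex), and `truth`.
#' @export
simulate_strata_and_counts <- function(regions, covariates, truth,
                                       reference_rates = default_reference_rates("nhl"),
                                       seed = 1L,
                                       pop_meanlog = log(120000),
                                       pop_sdlog = 0.8,
                                       populations = NULL) {
  stopifnot(inherits(regions, "region_map"), inherits(truth, "truth_record"))
  n <- regions$n_regions
  if (nrow(covariates) != n)
    stop("covariates must have one row per region", call. = FALSE)
  if (any(reference_rates$rate < 0) || any(!is.finite(reference_rates$rate)))
    stop("reference rates must be finite and non-negative", call. = FALSE)

  set.seed(derive_seed(seed, 4000))
  if (is.null(populations)) {
    totals <- pmin(pmax(stats::rlnorm(n, pop_meanlog, pop_sdlog), 10000), 1.1e6)
    sex_frac <- stats::runif(n, 0.49, 0.52)  # male share
    grid_rows <- expand.grid(age_group = AGE_GROUPS,
                             sex = c("male", "female"),
                             region = seq_len(n),
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
    grid_rows <- grid_rows[, c("region", "sex", "age_group")]
    pop_sex <- ifelse(grid_rows$sex == "male",
                      totals[grid_rows$region] * sex_frac[grid_rows$region],
                      totals[grid_rows$region] * (1 - sex_frac[grid_rows$region]))
    grid_rows$population <- round(pop_sex *
                                    AGE_PROPS[match(grid_rows$age_group, AGE_GROUPS)])
  } else {
    stopifnot(all(c("region", "sex", "age_group", "population") %in%
                    names(populations)))
    if (any(populations$population < 0))
      stop("populations must be non-negative", call. = FALSE)
    grid_rows <- populations[c("region", "sex", "age_group", "population")]
  }

  rate_key <- paste(reference_rates$sex, reference_rates$age_group)
  rate <- reference_rates$rate[match(paste(grid_rows$sex, grid_rows$age_group),
                                     rate_key)]
  if (anyNA(rate))
    stop("reference_rates do not cover all sex x age strata", call. = FALSE)

  u <- icar_sample(regions$adjacency, n, truth$sigma_u)
  v <- if (truth$sigma_v > 0) stats::rnorm(n, 0, truth$sigma_v) else numeric(n)

  smoke <- cbind(male = covariates$smoking_male,
                 female = covariates$smoking_female)
  smoke_c <- sweep(smoke, 2, colMeans(smoke))
  log_theta <- truth$alpha +
    truth$beta_radon * covariates$radon_true / 10 +
    truth$beta_deprivation * covariates$deprivation + u + v
  theta <- cbind(male = exp(log_theta + truth$beta_smoking * smoke_c[, "male"]),
                 female = exp(log_theta + truth$beta_smoking * smoke_c[, "female"]))

  lam <- grid_rows$population * rate *
    theta[cbind(grid_rows$region,
                ifelse(grid_rows$sex == "male", 1L, 2L))]
  grid_rows$observed <- stats::rpois(nrow(grid_rows), lam)
  over <- grid_rows$observed > grid_rows$population
  if (any(over))
    stop("simulated cases exceed population in ", sum(over),
         " strata; rates are implausibly high", call. = FALSE)

  structure(grid_rows, class = c("strata_table", "data.frame"),
            u = u, v = v, theta = theta, truth = truth)
}
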
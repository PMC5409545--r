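# Bayesian hierarchical spatial Poisson regression: Besag intrinsic CAR
# spatial effect plus unstructured heterogeneity (the BYM convolution),
# log-linear in region covariates with the expected count as offset,
# fitted by adaptive Metropolis-within-Gibbs.

#' Quintile grouping of a continuous regional score
#'
#' Rank-based quintiles: with ranks 1..n (ties broken by first occurrence),
#' region `i` falls in quintile `floor(5 * (rank_i - 1) / n) + 1`. For
#' n = 234 this yields group sizes 47, 47, 47, 47, 46.
#'
#' @param z numeric vector (e.g. deprivation z-scores).
#' @return integer vector of quintiles 1..5.
#' @export
assign_quintiles <- function(z) {
  stopifnot(is.numeric(z), length(z) >= 5)
  r <- rank(z, ties.method = "first")
  as.integer(floor(5 * (r - 1) / length(z)) + 1L)
}

#' Build the regression design matrix
#'
#' The radon column is concentration divided by 10, so `exp(beta)` is the
#' relative risk per 10 Bq/m3 increase. The crude model has the radon
#' column only. The adjusted model adds the sex-specific smoking rate
#' (mean-centered, continuous) and four indicator columns for deprivation
#' quintiles 2-5 (quintile 1 is the reference).
#'
#' @param radon region radon concentrations (Bq/m3), one per region.
#' @param covariates data.frame with `deprivation` and
#'   `smoking_male` / `smoking_female` columns (e.g. from
#'   [simulate_region_covariates()]); only needed when `adjusted = TRUE`.
#' @param sex `"male"` or `"female"` (selects the smoking column).
#' @param adjusted add confounder columns (default `FALSE` = crude model).
#' @return a numeric design matrix with named columns.
#' @export
build_design <- function(radon, covariates = NULL, sex = "male",
                         adjusted = FALSE) {
  stopifnot(is.numeric(radon), all(is.finite(radon)), all(radon >= 0))
  X <- cbind(radon10 = radon / 10)
  if (adjusted) {
    stopifnot(!is.null(covariates), nrow(covariates) == length(radon),
              sex %in% c("male", "female"))
    smoke <- covariates[[paste0("smoking_", sex)]]
    if (any(smoke < 0 | smoke > 100))
      stop("smoking rates must lie in [0, 100]", call. = FALSE)
    q <- assign_quintiles(covariates$deprivation)
    di <- sapply(2:5, function(k) as.numeric(q == k))
    colnames(di) <- paste0("di_q", 2:5)
    if (all(di == 0))
      warning("all regions fall in deprivation quintile 1; indicator columns are degenerate")
    X <- cbind(X, smoking = smoke - mean(smoke), di)
  }
  qr_rank <- qr(X)$rank
  if (qr_rank < ncol(X)) {
    drop_candidates <- colnames(X)[qr(X)$pivot[(qr_rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_candidates, collapse = ", "), call. = FALSE)
  }
  X
}

#' Prior settings for the CAR model
#'
#' Regression coefficients get independent mean-zero normal priors with a
#' very large variance (non-informative); both precision parameters get
#' Gamma hyperpriors, by default the WinBUGS-era Gamma(0.5, 0.0005)
#' convention. `alpha_prior = "flat_rate"` replaces the normal prior on the
#' intercept by a prior flat on `exp(alpha)` (useful for closed-form
#' conjugate checks).
#'
#' @param beta_var prior variance of intercept and coefficients (default 1e6).
#' @param tau_shape,tau_rate Gamma hyperprior for `tau_u` and `tau_v`.
#' @param alpha_prior `"normal"` (default) or `"flat_rate"`.
#' @return a list of class `car_priors`.
#' @export
car_priors <- function(beta_var = 1e6, tau_shape = 0.5, tau_rate = 5e-4,
                       alpha_prior = c("normal", "flat_rate")) {
  alpha_prior <- match.arg(alpha_prior)
  stopifnot(beta_var > 0, tau_shape > 0, tau_rate > 0)
  structure(list(beta_var = beta_var, tau_shape = tau_shape,
                 tau_rate = tau_rate, alpha_prior = alpha_prior),
            class = "car_priors")
}

#' Specify the BYM Poisson disease-mapping model
#'
#' Model: `O_i ~ Poisson(E_i * exp(alpha + x_i' beta + u_i + v_i))` with `u`
#' a Besag intrinsic CAR effect (pairwise-difference prior, sum-to-zero) and
#' `v` iid normal heterogeneity; either random-effect block can be switched
#' off.
#'
#' @param observed,expected per-region observed and expected counts
#'   (`expected > 0`).
#' @param X design matrix from [build_design()] (may have zero columns for
#'   an intercept-only model).
#' @param adjacency two-column matrix of unordered region pairs (the CAR
#'   neighborhood); must be connected when `include_u = TRUE`.
#' @param priors a [car_priors()] object.
#' @param include_u,include_v include the structured / unstructured random
#'   effect (defaults TRUE).
#' @return a list of class `car_model_spec`.
#' @export
car_model_spec <- function(observed, expected, X, adjacency,
                           priors = car_priors(), include_u = TRUE,
                           include_v = TRUE) {
  n <- length(observed)
  X <- as.matrix(X)
  if (nrow(X) == 0 && ncol(X) == 0) X <- matrix(0, n, 0)
  stopifnot(length(expected) == n, nrow(X) == n,
            inherits(priors, "car_priors"))
  if (any(expected <= 0)) stop("expected counts must be positive", call. = FALSE)
  if (any(observed < 0) || any(observed != floor(observed)))
    stop("observed counts must be non-negative integers", call. = FALSE)
  if (ncol(X) > 0 && qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  if (include_u) {
    if (is.null(adjacency) || nrow(adjacency) == 0)
      stop("include_u = TRUE requires a non-empty adjacency", call. = FALSE)
    if (any(adjacency[, 1] == adjacency[, 2]))
      stop("adjacency must be irreflexive", call. = FALSE)
    if (!adjacency_connected(adjacency, n))
      stop("CAR adjacency graph must be connected", call. = FALSE)
  }
  structure(list(observed = as.numeric(observed),
                 expected = as.numeric(expected), X = X,
                 adjacency = adjacency, priors = priors,
                 include_u = include_u, include_v = include_v,
                 n = n),
            class = "car_model_spec")
}

# Greedy graph coloring (descending degree): sites within one color class
# are mutually non-adjacent, so their single-site CAR updates are
# conditionally independent and can be done as one vectorized block.
color_graph <- function(adjacency, n) {
  nbr <- vector("list", n)
  for (r in seq_len(nrow(adjacency))) {
    i <- adjacency[r, 1]; j <- adjacency[r, 2]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  deg <- lengths(nbr)
  color <- integer(n)
  for (v in order(deg, decreasing = TRUE)) {
    used <- color[nbr[[v]]]
    color[v] <- setdiff(seq_len(max(used, 0) + 1L), used)[1L]
  }
  split(seq_len(n), color)
}

icar_pairwise_ss <- function(u, adjacency) {
  if (is.null(adjacency) || nrow(adjacency) == 0) return(0)
  sum((u[adjacency[, 1]] - u[adjacency[, 2]])^2)
}

#' Log posterior density of the BYM model (up to a constant)
#'
#' Poisson likelihood plus: normal (or flat-on-rate) prior for the
#' intercept, normal priors for coefficients, the intrinsic CAR
#' pairwise-difference prior
#' `(n - 1)/2 * log(tau_u) - tau_u / 2 * sum_{i~j} (u_i - u_j)^2`,
#' iid normal prior for `v`, and Gamma hyperpriors on the precisions.
#' Returns `-Inf` (never an error) for a non-finite linear predictor.
#'
#' @param state list with `alpha`, `beta`, `u`, `v`, `tau_u`, `tau_v`.
#' @param spec a [car_model_spec()].
#' @return scalar log posterior.
#' @export
log_posterior <- function(state, spec) {
  n <- spec$n
  u <- state$u %||% numeric(n)
  v <- state$v %||% numeric(n)
  beta <- state$beta %||% numeric(ncol(spec$X))
  eta <- state$alpha + as.numeric(spec$X %*% beta) + u + v
  if (any(!is.finite(eta))) return(-Inf)
  lp <- sum(stats::dpois(spec$observed, spec$expected * exp(eta), log = TRUE))
  pr <- spec$priors
  lp <- lp + if (pr$alpha_prior == "flat_rate") state$alpha else
    -state$alpha^2 / (2 * pr$beta_var)
  if (length(beta)) lp <- lp - sum(beta^2) / (2 * pr$beta_var)
  if (spec$include_u) {
    lp <- lp + (n - 1) / 2 * log(state$tau_u) -
      state$tau_u / 2 * icar_pairwise_ss(u, spec$adjacency) +
      (pr$tau_shape - 1) * log(state$tau_u) - pr$tau_rate * state$tau_u
  }
  if (spec$include_v) {
    lp <- lp + n / 2 * log(state$tau_v) - state$tau_v / 2 * sum(v^2) +
      (pr$tau_shape - 1) * log(state$tau_v) - pr$tau_rate * state$tau_v
  }
  if (!is.finite(lp)) return(-Inf)
  lp
}

#' MCMC settings
#'
#' Defaults follow common disease-mapping practice: five parallel chains of
#' 20,000 iterations each, the first 5,000 discarded as burn-in, and every
#' fifth retained thereafter.
#'
#' @param n_chains number of parallel chains (default 5).
#' @param n_iter iterations per chain (default 20000).
#' @param burn_in burn-in iterations discarded (default 5000, `< n_iter`).
#' @param thin keep every `thin`-th post-burn-in iteration (default 5).
#' @param seed integer run seed; per-chain streams are derived from it.
#' @param target_accept Robbins--Monro target acceptance rate for scalar
#'   and single-site proposals (default 0.44).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 5, n_iter = 20000, burn_in = 5000,
                        thin = 5, seed = 1L, target_accept = 0.44) {
  stopifnot(is_count(n_chains), n_chains >= 1, is_count(n_iter),
            is_count(burn_in), burn_in >= 0, burn_in < n_iter,
            is_count(thin), thin >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept),
            class = "mcmc_config")
}

#' Fit the BYM model by adaptive Metropolis-within-Gibbs
#'
#' Per sweep: random-walk Metropolis updates for the intercept and each
#' coefficient; vectorized single-site Metropolis updates for `u` (by graph
#' color class, so sites updated together are conditionally independent)
#' and for `v`; conjugate Gibbs draws for `tau_u` and `tau_v`. After each
#' sweep `u` is recentred to sum to zero with the mean absorbed into the
#' intercept (the identified parameterization; the linear predictor is
#' unchanged). Proposal scales adapt by Robbins--Monro with a decaying
#' rate. Chains are run sequentially with seeds derived from
#' `config$seed`, so identical configurations reproduce identical draws.
#'
#' @param spec a [car_model_spec()].
#' @param config an [mcmc_config()].
#' @return an object of class `car_fit`: list with `chains` (one matrix of
#'   thinned draws per chain; columns `alpha`, coefficient names, `tau_u`,
#'   `tau_v` as applicable), `accept` (acceptance rates), `spec`, `config`.
#' @export
mcmc_run <- function(spec, config = mcmc_config()) {
  stopifnot(inherits(spec, "car_model_spec"), inherits(config, "mcmc_config"))
  n <- spec$n
  O <- spec$observed; E <- spec$expected; X <- spec$X
  p <- ncol(X)
  pr <- spec$priors
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  if (n_keep < 1)
    stop("no iterations retained after burn-in and thinning", call. = FALSE)

  par_names <- c("alpha", colnames(X) %||% character(0),
                 if (spec$include_u) "tau_u", if (spec$include_v) "tau_v")
  if (p > 0 && is.null(colnames(X)))
    par_names <- c("alpha", paste0("beta", seq_len(p)),
                   if (spec$include_u) "tau_u", if (spec$include_v) "tau_v")

  colors <- if (spec$include_u) color_graph(spec$adjacency, n) else list()
  A <- if (spec$include_u)
    Matrix::sparseMatrix(i = c(spec$adjacency[, 1], spec$adjacency[, 2]),
                         j = c(spec$adjacency[, 2], spec$adjacency[, 1]),
                         x = 1, dims = c(n, n)) else NULL
  deg <- if (spec$include_u) as.numeric(Matrix::rowSums(A)) else NULL
  A_color <- lapply(colors, function(S) A[S, , drop = FALSE])

  alpha0 <- log(sum(O) / sum(E))
  if (!is.finite(alpha0)) alpha0 <- 0
  chains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, 100 + ch))
    off <- ch - (config$n_chains + 1) / 2  # chain-indexed over-dispersion
    alpha <- alpha0 + 0.15 * off
    beta <- rep(0.03 * off, p)
    u <- numeric(n); v <- numeric(n)
    tau_u <- pr$tau_shape / pr$tau_rate * exp(0.5 * off)
    tau_v <- pr$tau_shape / pr$tau_rate * exp(-0.5 * off)
    eta <- alpha + as.numeric(X %*% beta)
    if (!all(is.finite(exp(eta) * E)))
      stop("non-finite posterior at initialization", call. = FALSE)
    ee <- E * exp(eta)

    ls_a <- log(0.1); ls_b <- rep(log(0.05), p)
    ls_u <- rep(log(0.5), n); ls_v <- rep(log(0.5), n)
    acc_a <- 0; acc_b <- numeric(p); acc_u <- 0; acc_v <- 0
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    kept <- 0L

    for (t in seq_len(config$n_iter)) {
      gam <- 1 / t^0.6  # Robbins-Monro decay

      ## intercept
      da <- exp(ls_a) * stats::rnorm(1)
      dlik <- sum(O) * da - (exp(da) - 1) * sum(ee)
      dpri <- if (pr$alpha_prior == "flat_rate") da else
        (alpha^2 - (alpha + da)^2) / (2 * pr$beta_var)
      ap <- min(1, exp(dlik + dpri))
      if (stats::runif(1) < ap) {
        alpha <- alpha + da; ee <- ee * exp(da); acc_a <- acc_a + 1
      }
      ls_a <- ls_a + gam * (ap - config$target_accept)

      ## coefficients
      for (j in seq_len(p)) {
        db <- exp(ls_b[j]) * stats::rnorm(1)
        deta <- db * X[, j]
        ee_new <- ee * exp(deta)
        dlik <- sum(O * deta) - sum(ee_new - ee)
        dpri <- (beta[j]^2 - (beta[j] + db)^2) / (2 * pr$beta_var)
        ap <- min(1, exp(dlik + dpri))
        if (stats::runif(1) < ap) {
          beta[j] <- beta[j] + db; ee <- ee_new; acc_b[j] <- acc_b[j] + 1
        }
        ls_b[j] <- ls_b[j] + gam * (ap - config$target_accept)
      }

      ## structured effect u, by color class
      if (spec$include_u) {
        for (ci in seq_along(colors)) {
          S <- colors[[ci]]
          du <- exp(ls_u[S]) * stats::rnorm(length(S))
          Au_S <- as.numeric(A_color[[ci]] %*% u)
          ee_new <- ee[S] * exp(du)
          dlik <- O[S] * du - (ee_new - ee[S])
          dpri <- -tau_u / 2 *
            (deg[S] * ((u[S] + du)^2 - u[S]^2) - 2 * du * Au_S)
          ap <- pmin(1, exp(dlik + dpri))
          acc_i <- stats::runif(length(S)) < ap
          u[S][acc_i] <- u[S][acc_i] + du[acc_i]
          ee[S][acc_i] <- ee_new[acc_i]
          acc_u <- acc_u + sum(acc_i)
          ls_u[S] <- ls_u[S] + gam * (ap - config$target_accept)
        }
        ## recentre: absorb the mean into the intercept (eta unchanged)
        mb <- mean(u)
        u <- u - mb
        alpha <- alpha + mb
        ## Gibbs: tau_u
        tau_u <- stats::rgamma(1, pr$tau_shape + (n - 1) / 2,
                               pr$tau_rate + icar_pairwise_ss(u, spec$adjacency) / 2)
      }

      ## unstructured effect v (conditionally independent sites)
      if (spec$include_v) {
        dv <- exp(ls_v) * stats::rnorm(n)
        ee_new <- ee * exp(dv)
        dlik <- O * dv - (ee_new - ee)
        dpri <- -tau_v / 2 * ((v + dv)^2 - v^2)
        ap <- pmin(1, exp(dlik + dpri))
        acc_i <- stats::runif(n) < ap
        v[acc_i] <- v[acc_i] + dv[acc_i]
        ee[acc_i] <- ee_new[acc_i]
        acc_v <- acc_v + sum(acc_i)
        ls_v <- ls_v + gam * (ap - config$target_accept)
        tau_v <- stats::rgamma(1, pr$tau_shape + n / 2,
                               pr$tau_rate + sum(v^2) / 2)
      }

      if (t > config$burn_in && (t - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- c(alpha, beta,
                           if (spec$include_u) tau_u,
                           if (spec$include_v) tau_v)
      }
    }
    chains[[ch]] <- draws
    attr(chains[[ch]], "final_state") <-
      list(alpha = alpha, beta = beta, u = u, v = v,
           tau_u = if (spec$include_u) tau_u, tau_v = if (spec$include_v) tau_v)
    rates <- c(alpha = acc_a / config$n_iter,
               if (p > 0) stats::setNames(acc_b / config$n_iter,
                                          par_names[1 + seq_len(p)]),
               u = if (spec$include_u) acc_u / (config$n_iter * n) else NA,
               v = if (spec$include_v) acc_v / (config$n_iter * n) else NA)
    bad <- rates[!is.na(rates)]
    bad <- bad[bad < 0.1 | bad > 0.6]
    if (length(bad))
      warning(sprintf("chain %d: acceptance rate outside [0.1, 0.6] for %s",
                      ch, paste(names(bad), collapse = ", ")), call. = FALSE)
    accept[[ch]] <- rates
  }
  structure(list(chains = chains, accept = accept, spec = spec,
                 config = config, par_names = par_names),
            class = "car_fit")
}

#' @export
print.car_fit <- function(x, ...) {
  cat(sprintf("car_fit: %d chains x %d thinned draws of (%s)\n",
              length(x$chains), nrow(x$chains[[1]]),
              paste(x$par_names, collapse = ", ")))
  invisible(x)
}

#' Gelman--Rubin potential scale reduction factor
#'
#' `R_hat = sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B = n * var(chain means)` the between-chain variance
#' (the classical split-free variant).
#'
#' @param chains list of at least two equal-length numeric vectors
#'   (length >= 2).
#' @return the scalar `R_hat`.
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2)
    stop("chains must have equal lengths >= 2", call. = FALSE)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) stop("degenerate chains: zero within-chain variance", call. = FALSE)
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Geyer-style initial-positive-sequence effective sample size (per chain,
# summed over chains).
ess_chain <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0; k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Summarize posterior draws as relative risks
#'
#' Pools post-burn-in thinned draws across chains and reports, per
#' parameter, the posterior mean / median / equal-tailed 2.5% and 97.5%
#' quantiles on the log-RR scale, the same on the RR scale
#' (`rr_* = transform(log_*)` for the quantiles, and the posterior mean of
#' the transformed draws for `rr_mean`), the Gelman--Rubin `R_hat` across
#' chains, and an effective sample size. Quantiles use linear interpolation
#' (R type 7).
#'
#' @param fit a `car_fit` from [mcmc_run()].
#' @param params parameters to summarize (default: intercept and
#'   coefficients, not the precisions).
#' @param transform monotone map from the linear-predictor scale to the
#'   reporting scale (default `exp`, giving relative risks).
#' @param min_draws minimum pooled draws required (default 100).
#' @return a data.frame, one row per parameter.
#' @export
summarize_posterior <- function(fit, params = NULL, transform = exp,
                                min_draws = 100) {
  stopifnot(inherits(fit, "car_fit"))
  if (is.null(params))
    params <- setdiff(fit$par_names, c("tau_u", "tau_v"))
  n_pool <- sum(vapply(fit$chains, nrow, integer(1)))
  if (n_pool < min_draws)
    stop(sprintf("only %d pooled draws; at least %d required", n_pool,
                 min_draws), call. = FALSE)
  out <- lapply(params, function(pn) {
    per_chain <- lapply(fit$chains, function(m) m[, pn])
    x <- unlist(per_chain, use.names = FALSE)
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    rhat <- if (length(fit$chains) >= 2)
      tryCatch(gelman_rubin(per_chain), error = function(e) NA_real_)
    else NA_real_
    data.frame(parameter = pn,
               mean_log = mean(x), median_log = q[2],
               q2.5_log = q[1], q97.5_log = q[3],
               rr_mean = mean(transform(x)),
               rr_median = transform(q[2]),
               rr_q2.5 = transform(q[1]), rr_q97.5 = transform(q[3]),
               rhat = rhat,
               ess = sum(vapply(per_chain, ess_chain, numeric(1))))
  })
  do.call(rbind, out)
}
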
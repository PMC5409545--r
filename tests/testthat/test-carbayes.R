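test_that("quintile grouping splits 234 scores into 47/47/47/47/46", {
  set.seed(7)
  q <- assign_quintiles(rnorm(234))
  expect_equal(as.integer(table(q)), c(47L, 47L, 47L, 47L, 46L))
  # ties broken by first occurrence: a constant vector still partitions
  qt <- assign_quintiles(rep(1, 10))
  expect_equal(as.integer(table(qt)), rep(2L, 5))
})

test_that("the design matrix encodes radon per 10 Bq/m3 and confounders", {
  X <- build_design(c(57, 110))
  expect_equal(unname(X[, "radon10"]), c(5.7, 11))
  expect_equal(colnames(X), "radon10")

  cov <- simulate_region_covariates(100, seed = 3)
  Xa <- build_design(cov$radon_true, cov, sex = "female", adjusted = TRUE)
  expect_equal(colnames(Xa),
               c("radon10", "smoking", "di_q2", "di_q3", "di_q4", "di_q5"))
  expect_equal(mean(Xa[, "smoking"]), 0, tolerance = 1e-12)  # centered
  expect_true(all(Xa[, paste0("di_q", 2:5)] %in% c(0, 1)))
  # quintile 1 is the reference: exactly 4/5 of regions carry an indicator
  expect_equal(sum(rowSums(Xa[, paste0("di_q", 2:5)])), 80)
  # collinear columns are named in the error
  cov2 <- cov; cov2$deprivation <- rep(1:5, each = 20)  # aligns with nothing
  expect_error(
    car_model_spec(rep(1, 100), rep(1, 100),
                   cbind(Xa, dup = Xa[, "radon10"]), NULL,
                   include_u = FALSE, include_v = FALSE),
    "rank deficient")
})

test_that("log posterior reduces to the closed Poisson form at the origin", {
  O <- c(3, 5, 2); E <- c(2.5, 6, 1.5)
  spec <- car_model_spec(O, E, matrix(0, 3, 0), NULL,
                         include_u = FALSE, include_v = FALSE)
  st <- list(alpha = 0, beta = numeric(0), u = numeric(3), v = numeric(3),
             tau_u = 1, tau_v = 1)
  expect_equal(log_posterior(st, spec),
               sum(O * log(E) - E - lgamma(O + 1)), tolerance = 1e-12)
})

test_that("log posterior equals a hand-summed term-by-term evaluation", {
  # 3-region chain graph 1-2-3
  O <- c(4, 7, 1); E <- c(3, 8, 2)
  X <- cbind(radon10 = c(2.4, 5.7, 9.1))
  adj <- rbind(c(1L, 2L), c(2L, 3L))
  pr <- car_priors()
  spec <- car_model_spec(O, E, X, adj, priors = pr)
  st <- list(alpha = 0.2, beta = 0.05, u = c(0.1, -0.3, 0.2),
             v = c(-0.05, 0, 0.05), tau_u = 2.5, tau_v = 4)
  eta <- st$alpha + 0.05 * X[, 1] + st$u + st$v
  hand <- sum(O * log(E * exp(eta)) - E * exp(eta) - lgamma(O + 1)) -
    st$alpha^2 / (2 * pr$beta_var) -
    st$beta^2 / (2 * pr$beta_var) +
    (3 - 1) / 2 * log(st$tau_u) -
    st$tau_u / 2 * ((0.1 - (-0.3))^2 + ((-0.3) - 0.2)^2) +
    (pr$tau_shape - 1) * log(st$tau_u) - pr$tau_rate * st$tau_u +
    3 / 2 * log(st$tau_v) - st$tau_v / 2 * sum(st$v^2) +
    (pr$tau_shape - 1) * log(st$tau_v) - pr$tau_rate * st$tau_v
  expect_equal(log_posterior(st, spec), hand, tolerance = 1e-12)
})

test_that("adding a constant to u shifts only the likelihood", {
  O <- c(4, 7, 1); E <- c(3, 8, 2)
  adj <- rbind(c(1L, 2L), c(2L, 3L))
  spec <- car_model_spec(O, E, matrix(0, 3, 0), adj, include_v = FALSE)
  st1 <- list(alpha = 0, beta = numeric(0), u = c(0.1, -0.3, 0.2),
              v = numeric(3), tau_u = 2, tau_v = 1)
  st2 <- st1; st2$u <- st1$u + 0.7
  dlik <- sum(dpois(O, E * exp(st2$u), log = TRUE)) -
    sum(dpois(O, E * exp(st1$u), log = TRUE))
  expect_equal(log_posterior(st2, spec) - log_posterior(st1, spec), dlik,
               tolerance = 1e-10)
  # and the acceptance log-ratio is exactly reciprocal
  f <- log_posterior(st2, spec) - log_posterior(st1, spec)
  b <- log_posterior(st1, spec) - log_posterior(st2, spec)
  expect_equal(f, -b, tolerance = 1e-12)
  # a non-finite linear predictor returns -Inf, never an error
  st3 <- st1; st3$u[1] <- Inf
  expect_identical(log_posterior(st3, spec), -Inf)
})

test_that("Gelman-Rubin matches its formula in forced scenarios", {
  set.seed(12)
  # iid chains from a common distribution converge to R-hat near 1
  chains <- replicate(4, rnorm(10000), simplify = FALSE)
  expect_gt(gelman_rubin(chains), 0.99)
  expect_lt(gelman_rubin(chains), 1.01)
  # two separated chains: direct-formula oracle, far above 1.1
  n <- 1000
  c1 <- rnorm(n, 0, 1); c2 <- rnorm(n, 100, 1)
  W <- (var(c1) + var(c2)) / 2
  B <- n * var(c(mean(c1), mean(c2)))
  expect_equal(gelman_rubin(list(c1, c2)),
               sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)
  expect_gt(gelman_rubin(list(c1, c2)), 10)
  # a duplicated chain has B = 0, hence R-hat = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(c1, c1)), sqrt((n - 1) / n),
               tolerance = 1e-12)
  expect_error(gelman_rubin(list(rep(1, 10), rep(1, 10))), "degenerate")
  expect_error(gelman_rubin(list(c1)), "at least 2")
})

test_that("posterior summaries transform quantiles monotonically", {
  mk_fit <- function(draws_list) {
    structure(list(chains = lapply(draws_list, function(x)
      matrix(x, ncol = 1, dimnames = list(NULL, "radon10"))),
      par_names = "radon10"), class = "car_fit")
  }
  # constant draws at log(1.07)
  fit <- mk_fit(list(rep(log(1.07), 200), rep(log(1.07), 200)))
  sm <- summarize_posterior(fit)
  expect_equal(sm$rr_mean, 1.07)
  expect_equal(sm$rr_q2.5, 1.07)
  expect_equal(sm$rr_q97.5, 1.07)
  # normal draws: CrI matches the closed-form normal quantiles
  set.seed(3)
  x <- rnorm(100000, 0, 0.01)
  sm2 <- summarize_posterior(mk_fit(list(x[1:50000], x[50001:100000])))
  expect_equal(sm2$rr_q2.5, exp(-0.0196), tolerance = 0.002)
  expect_equal(sm2$rr_q97.5, exp(0.0196), tolerance = 0.002)
  # RR quantiles are exactly exp of the log-scale quantiles
  expect_identical(sm2$rr_q2.5, exp(sm2$q2.5_log))
  expect_identical(sm2$rr_q97.5, exp(sm2$q97.5_log))
  # too few draws is an error
  expect_error(summarize_posterior(mk_fit(list(rnorm(10)))), "at least")
})

test_that("the sampler is deterministic and refuses empty retention", {
  O <- c(12, 20, 9, 15); E <- c(10, 18, 11, 14)
  adj <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(1L, 4L))
  spec <- car_model_spec(O, E, cbind(radon10 = c(3, 5, 7, 9)), adj)
  cfg <- mcmc_config(n_chains = 2, n_iter = 400, burn_in = 100, thin = 2,
                     seed = 5)
  f1 <- suppressWarnings(mcmc_run(spec, cfg))
  f2 <- suppressWarnings(mcmc_run(spec, cfg))
  expect_identical(f1$chains, f2$chains)
  expect_error(mcmc_run(spec, mcmc_config(n_chains = 1, n_iter = 10,
                                          burn_in = 9, thin = 5, seed = 1)),
               "retained")
})

test_that("the structured effect stays on the sum-to-zero subspace", {
  g <- toy_grid(4, 4)
  rmap <- make_regions(g, 6, seed = 8)
  set.seed(8)
  O <- rpois(6, 20) + 1; E <- rep(20, 6)
  spec <- car_model_spec(O, E, matrix(0, 6, 0), rmap$adjacency)
  fit <- suppressWarnings(
    mcmc_run(spec, mcmc_config(2, 600, 100, 5, seed = 9)))
  for (ch in fit$chains) {
    fs <- attr(ch, "final_state")
    expect_lt(abs(sum(fs$u)), 1e-10)
    expect_true(all(is.finite(ch[, "tau_u"]) & ch[, "tau_u"] > 0))
  }
})
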
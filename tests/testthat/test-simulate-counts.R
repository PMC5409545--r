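test_that("ICAR draws live on the sum-to-zero subspace", {
  g <- toy_grid(6, 6)
  rmap <- make_regions(g, 12, seed = 3)
  set.seed(99)
  for (i in 1:10) {
    u <- icar_sample(rmap$adjacency, 12, sigma_u = 0.5)
    expect_lt(abs(sum(u)), 1e-10)
    expect_gt(stats::sd(u), 0)
  }
  expect_equal(icar_sample(rmap$adjacency, 12, 0), numeric(12))
})

test_that("with all effects zero, observed totals are unbiased for expected", {
  g <- toy_grid(6, 6)
  rmap <- make_regions(g, 10, seed = 1)
  cov <- simulate_region_covariates(10, seed = 1)
  tr <- truth_record(alpha = 0, beta_radon = 0, sigma_u = 0, sigma_v = 0)
  rates <- default_reference_rates("nhl")
  rate_of <- function(st) rates$rate[match(paste(st$sex, st$age_group),
                                           paste(rates$sex, rates$age_group))]
  ratio <- vapply(seq_len(1000), function(r) {
    st <- simulate_strata_and_counts(rmap, cov, tr, rates, seed = r)
    sum(st$observed) / sum(st$population * rate_of(st))
  }, numeric(1))
  expect_gt(mean(ratio), 0.99)
  expect_lt(mean(ratio), 1.01)
})

test_that("without random effects the counts are pure Poisson", {
  g <- toy_grid(4, 4)
  rmap <- make_regions(g, 4, seed = 2)
  cov <- simulate_region_covariates(4, seed = 2)
  tr <- truth_record(alpha = 0, beta_radon = 0, sigma_u = 0, sigma_v = 0)
  rates <- default_reference_rates("lung")
  # condition on one fixed population, then replicate the count draws:
  # region totals have variance/mean ~ 1 for a pure Poisson mechanism
  pops <- as.data.frame(simulate_strata_and_counts(rmap, cov, tr, rates,
                                                   seed = 1))
  pops <- pops[c("region", "sex", "age_group", "population")]
  totals <- vapply(seq_len(600), function(r) {
    st <- simulate_strata_and_counts(rmap, cov, tr, rates, seed = 5000 + r,
                                     populations = pops)
    sum(st$observed[st$region == 1])
  }, numeric(1))
  expect_gt(var(totals) / mean(totals), 0.85)
  expect_lt(var(totals) / mean(totals), 1.15)
})

test_that("strata tables respect structural invariants and determinism", {
  g <- toy_grid(6, 6)
  rmap <- make_regions(g, 8, seed = 4)
  cov <- simulate_region_covariates(8, seed = 4)
  tr <- truth_record(beta_radon = log(1.07), sigma_u = 0.1, sigma_v = 0.1)
  st <- simulate_strata_and_counts(rmap, cov, tr, seed = 11)
  expect_true(all(st$observed <= st$population))
  expect_true(all(st$observed >= 0))
  expect_equal(nrow(st), 8 * 2 * 17)          # region x sex x age group
  expect_gt(min(rowsum(st$population, st$region)), 0)
  expect_lt(abs(sum(attr(st, "u"))), 1e-10)
  st2 <- simulate_strata_and_counts(rmap, cov, tr, seed = 11)
  expect_identical(as.data.frame(st), as.data.frame(st2))
  # negative rates are refused
  bad <- default_reference_rates("nhl"); bad$rate[1] <- -1
  expect_error(simulate_strata_and_counts(rmap, cov, tr, bad, seed = 1),
               "non-negative")
})

test_that("covariates stay inside their documented ranges", {
  cov <- simulate_region_covariates(234, seed = 6)
  expect_true(all(cov$smoking_male >= 31.9 & cov$smoking_male <= 62.4))
  expect_true(all(cov$smoking_female >= 0.4 & cov$smoking_female <= 12.5))
  expect_true(all(cov$radon_true > 0))
  expect_equal(nrow(cov), 234)
})

test_that("true region radon is the cell mean of the exponentiated field", {
  g <- toy_grid(4, 4)
  rmap <- make_regions(g, 4, method = "blocks")
  f <- log(seq(10, 160, by = 10))
  rt <- region_true_radon(f, rmap)
  brute <- sapply(1:4, function(r) mean(exp(f)[rmap$membership == r]))
  expect_equal(rt, brute)
})
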
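test_that("skewness matches its defining formula and symmetries", {
  # symmetric data
  expect_equal(skewness(c(1, 2, 3)), 0)
  expect_equal(skewness(c(-5, 0, 5, 0)), 0)
  # direct brute-force evaluation of the adjusted Fisher-Pearson form
  x <- c(1, 1, 1, 10)
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / n
  m3 <- sum((x - mean(x))^3) / n
  expect_equal(skewness(x), (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2),
               tolerance = 1e-12)
  # antisymmetry under reflection
  y <- c(0.3, 1.9, 2.2, 7.5, 0.1)
  expect_equal(skewness(-y), -skewness(y), tolerance = 1e-12)
  # guards
  expect_error(skewness(c(1, 2)), "at least 3")
  expect_error(skewness(rep(4, 10)), "zero-variance")
})

test_that("empirical semivariogram reproduces hand-enumerated pairs", {
  # equal values at distance 1 -> zero semivariance in that bin
  e <- empirical_semivariogram(c(0, 1), c(0, 0), c(2, 2), n_lags = 2,
                               max_lag = 2)
  expect_equal(e$gamma[e$n_pairs > 0], 0)

  # collinear points at 0, 1, 2 km with values 0, 1, 0:
  # bin at h=1 has pairs (0,1),(1,2): gamma = (1 + 1) / (2*2) = 0.5
  # bin at h=2 has pair (0,2): gamma = 0
  e <- empirical_semivariogram(c(0, 1, 2), c(0, 0, 0), c(0, 1, 0),
                               n_lags = 2, max_lag = 2)
  expect_equal(e$n_pairs, c(2L, 1L))
  expect_equal(e$gamma, c(0.5, 0))

  # duplicate locations feed the zero-lag nugget tally, never a bin
  e <- empirical_semivariogram(c(0, 0, 3), c(0, 0, 0), c(1, 3, 2),
                               n_lags = 1, max_lag = 4)
  expect_equal(attr(e, "n_zero"), 1L)
  expect_equal(attr(e, "gamma_zero"), (3 - 1)^2 / 2)
  expect_equal(sum(e$n_pairs), 2L)  # only the two positive-lag pairs

  expect_error(empirical_semivariogram(c(0, 10), c(0, 0), c(1, 2),
                                       max_lag = 1), "beyond max_lag")
})

test_that("variogram model evaluation respects its contract", {
  m <- variogram_model("spherical", nugget = 0.2, psill = 0.8, range = 10)
  expect_equal(vgm_gamma(m, 0), 0)
  h <- seq(0.01, 30, length.out = 100)
  g <- vgm_gamma(m, h)
  expect_true(all(diff(g) >= -1e-12))          # nondecreasing
  expect_equal(vgm_gamma(m, 10), 1)            # sill reached at the range
  expect_equal(sill(m), 1)
  expect_equal(practical_range(variogram_model("exponential", 0, 1, 5)), 15)
})

test_that("weighted least squares recovers exact variogram parameters", {
  m0 <- variogram_model("spherical", nugget = 0.1, psill = 0.9, range = 30)
  h <- seq(2, 60, length.out = 12)
  emp <- data.frame(lag = h, gamma = vgm_gamma(m0, h),
                    n_pairs = rep(200L, length(h)))
  class(emp) <- c("empirical_variogram", "data.frame")
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-4)
  expect_equal(fit$psill, 0.9, tolerance = 1e-4)
  expect_equal(fit$range, 30, tolerance = 1e-3)
})

test_that("degenerate and misspecified variogram fits stay inside bounds", {
  # flat empirical variogram -> pure nugget
  emp <- data.frame(lag = 1:6, gamma = rep(0.7, 6), n_pairs = rep(50L, 6))
  class(emp) <- c("empirical_variogram", "data.frame")
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget + fit$psill * 0, fit$nugget)  # named access sanity
  expect_equal(fit$nugget, 0.7, tolerance = 1e-3)
  expect_lt(fit$psill, 1e-3)

  # exponential family on spherical truth: still a valid bounded model
  m0 <- variogram_model("spherical", nugget = 0.1, psill = 0.9, range = 30)
  h <- seq(2, 60, length.out = 12)
  emp2 <- data.frame(lag = h, gamma = vgm_gamma(m0, h),
                     n_pairs = rep(200L, length(h)))
  class(emp2) <- c("empirical_variogram", "data.frame")
  fit2 <- fit_variogram(emp2, "exponential")
  expect_s3_class(fit2, "variogram_model")
  expect_gte(fit2$nugget, 0)
  expect_gte(fit2$psill, 0)
  expect_gt(fit2$range, 0)

  expect_error(fit_variogram(emp[1:2, ], "spherical"), "3 nonempty")
})
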
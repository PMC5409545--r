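test_that("ordinary kriging is exact at data locations with zero nugget", {
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 5)
  x <- c(0, 3, 7); y <- c(0, 2, 1); v <- c(1.2, -0.5, 2.0)
  ok <- ordinary_kriging(x, y, v, m, x0 = 3, y0 = 2)
  expect_equal(ok$yhat, -0.5, tolerance = 1e-9)
  expect_equal(ok$sigma2, 0, tolerance = 1e-9)
})

test_that("production weights match an independent dense solve", {
  m <- variogram_model("exponential", nugget = 0.1, psill = 0.9, range = 4)
  # three collinear points with a target between them
  x <- c(0, 1, 2); y <- c(0, 0, 0); v <- c(0.3, 1.1, 0.5)
  ok <- ordinary_kriging(x, y, v, m, x0 = 0.6, y0 = 0)
  oracle <- ok_dense_oracle(x, y, v, m, 0.6, 0)
  expect_equal(ok$weights, oracle$weights, tolerance = 1e-10)
  expect_equal(ok$yhat, oracle$yhat, tolerance = 1e-10)
  expect_equal(ok$sigma2, oracle$sigma2, tolerance = 1e-10)
  expect_equal(ok$mu, oracle$mu, tolerance = 1e-10)
})

test_that("kriging weights sum to one and variances stay non-negative", {
  set.seed(41)
  m <- variogram_model("spherical", nugget = 0.2, psill = 0.8, range = 6)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    x <- runif(k, 0, 10); y <- runif(k, 0, 10); v <- rnorm(k)
    ok <- ordinary_kriging(x, y, v, m, runif(1, 0, 10), runif(1, 0, 10))
    expect_equal(sum(ok$weights), 1, tolerance = 1e-9)
    expect_gte(ok$sigma2, 0)
  }
})

test_that("a single neighbor forces weight one", {
  m <- variogram_model("exponential", nugget = 0.1, psill = 0.9, range = 4)
  ok <- ordinary_kriging(2, 3, 1.7, m, x0 = 5, y0 = 5)
  expect_equal(ok$weights, 1)
  expect_equal(ok$yhat, 1.7)
})

test_that("coincident data points are averaged, not fatal", {
  m <- variogram_model("exponential", nugget = 0.1, psill = 0.9, range = 4)
  ok <- ordinary_kriging(c(0, 0, 2), c(0, 0, 0), c(1, 3, 0), m, 1, 0)
  ok2 <- ordinary_kriging(c(0, 2), c(0, 0), c(2, 0), m, 1, 0)
  expect_equal(ok$yhat, ok2$yhat, tolerance = 1e-12)
})

test_that("lognormal back-transform limits, monotonicity and guards", {
  expect_equal(lognormal_backtransform(1.3, 0, 0), exp(1.3))
  z1 <- lognormal_backtransform(1.0, 0.4, 0.1)
  z2 <- lognormal_backtransform(1.5, 0.4, 0.1)
  expect_lt(z1, z2)
  expect_error(lognormal_backtransform(NaN, 0.1, 0), "non-finite")
  expect_error(lognormal_backtransform(0, -0.5, 0), "negative")
  expect_error(lognormal_backtransform(800, 0, 0), "overflow")
})

test_that("krige_grid composes per-cell kriging and flags empty neighborhoods", {
  sv <- small_survey(seed = 3, n_points = 80, nx = 12)
  y <- log(sv$survey$radon_bqm3)
  m <- variogram_model("exponential", nugget = 0.5, psill = 0.4, range = 3)
  kr <- krige_grid(sv$survey$x_km, sv$survey$y_km, y, m, sv$grid)
  expect_equal(nrow(kr), 144)
  expect_true(all(kr$zhat > 0))
  expect_true(all(kr$sigma2 >= 0))
  # independent single-cell check against ordinary_kriging
  cc <- cell_centers(sv$grid)
  i <- 40
  p <- radonmap:::dedupe_points(sv$survey$x_km, sv$survey$y_km, y)
  d2 <- (p$x - cc$x[i])^2 + (p$y - cc$y[i])^2
  nb <- order(d2)[1:min(16, sum(d2 <= (3 * practical_range(m))^2))]
  ok <- ordinary_kriging(p$x[nb], p$y[nb], p$values[nb], m, cc$x[i], cc$y[i])
  expect_equal(kr$yhat[i], ok$yhat, tolerance = 1e-12)
  # a tiny radius forces the global-mean fallback
  expect_message(
    kr2 <- krige_grid(sv$survey$x_km[1:3], sv$survey$y_km[1:3], y[1:3], m,
                      sv$grid, max_radius = 1e-6),
    "fallback")
  expect_true(all(kr2$fallback))
  expect_equal(unique(kr2$yhat), mean(y[1:3]))
})

test_that("regional aggregation is the arithmetic cell mean, bounded by extremes", {
  g <- grid_spec(4, 4)
  rmap <- make_regions(g, 4, method = "blocks")
  kr <- data.frame(cell = 1:16, zhat = rep(7, 16))
  agg <- aggregate_to_regions(kr, rmap)
  expect_equal(agg$radon, rep(7, 4))          # constant field preserved

  vals <- as.numeric(1:16)
  kr2 <- data.frame(cell = 1:16, zhat = vals)
  agg2 <- aggregate_to_regions(kr2, rmap)
  # brute-force row enumeration oracle
  brute <- sapply(1:4, function(r) mean(vals[rmap$membership == r]))
  expect_equal(agg2$radon, brute)
  for (r in 1:4) {
    expect_gte(agg2$radon[r], min(vals[rmap$membership == r]))
    expect_lte(agg2$radon[r], max(vals[rmap$membership == r]))
  }
  # the documented 4-cell example
  g1 <- grid_spec(2, 2)
  rmap1 <- region_map(rep(1L, 4), g1)
  expect_equal(aggregate_to_regions(
    data.frame(cell = 1:4, zhat = c(10, 20, 30, 40)), rmap1)$radon, 25)
})
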
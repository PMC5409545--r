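# Shared fixtures, built in code at test time.

toy_grid <- function(nx = 6, ny = 6) grid_spec(nx = nx, ny = ny)

# A tiny three-region strata table with hand-checkable numbers.
toy_strata <- function() {
  data.frame(
    region = rep(1:3, each = 4),
    sex = rep(rep(c("male", "female"), each = 2), 3),
    age_group = rep(c("0-4", "5-9"), 6),
    population = c(100, 200, 150, 250,
                   300, 100, 200, 100,
                   100, 100, 150, 150),
    observed = c(1, 4, 0, 5,
                 6, 2, 2, 1,
                 2, 1, 3, 2))
}

# A small calibrated field + survey, reused by several geostat tests.
small_survey <- function(seed = 1, n_points = 200, nx = 25) {
  g <- grid_spec(nx, nx)
  p <- calibrate_field_params()
  f <- simulate_log_field(g, p, seed = seed)
  sv <- sample_survey_points(f, g, n_points,
                             measurement_sd_log = p$measurement_sd_log,
                             seed = seed + 500)
  list(grid = g, params = p, field = f, survey = sv)
}

# Independent dense solve of the ordinary-kriging system, written directly
# from the block definition (the oracle for the production solver).
ok_dense_oracle <- function(x, y, values, model, x0, y0) {
  k <- length(x)
  G <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j)
      G[i, j] <- vgm_gamma(model, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  }
  g0 <- numeric(k)
  for (i in seq_len(k))
    g0[i] <- vgm_gamma(model, sqrt((x[i] - x0)^2 + (y[i] - y0)^2))
  A <- cbind(rbind(G, 1), c(rep(1, k), 0))
  sol <- qr.solve(A, c(g0, 1))
  list(weights = sol[1:k], mu = sol[k + 1],
       yhat = sum(sol[1:k] * values),
       sigma2 = sum(sol[1:k] * g0) + sol[k + 1])
}
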
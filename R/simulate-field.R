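# Simulation of the latent log-radon Gaussian random field and of survey
# point measurements drawn from it.

# Dense Cholesky factorization is used for the field covariance; the cell
# limit keeps the n x n matrix tractable on a desktop.
MAX_FIELD_CELLS <- 10000L

#' Parameters of the latent log-radon field
#'
#' @param mu_log mean of log-radon (log Bq/m3).
#' @param variogram a [variogram_model()] on the log scale describing the
#'   spatial structure of the latent field (its sill is the marginal
#'   log-scale variance of the field).
#' @param measurement_sd_log standard deviation of iid log-scale measurement
#'   noise added to survey values (>= 0); not part of the field itself.
#' @return an object of class `field_params`.
#' @export
field_params <- function(mu_log, variogram, measurement_sd_log = 0) {
  stopifnot(is.numeric(mu_log), is.finite(mu_log),
            inherits(variogram, "variogram_model"),
            is.numeric(measurement_sd_log), measurement_sd_log >= 0)
  structure(list(mu_log = as.numeric(mu_log), variogram = variogram,
                 measurement_sd_log = as.numeric(measurement_sd_log)),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf("field_params: mu_log %.4g (GM %.4g Bq/m3), measurement sd(log) %.4g\n",
              x$mu_log, exp(x$mu_log), x$measurement_sd_log))
  print(x$variogram)
  invisible(x)
}

# Lognormal skewness as a function of the log-scale variance s2:
# (exp(s2) + 2) * sqrt(exp(s2) - 1).
lognormal_skewness <- function(s2) (exp(s2) + 2) * sqrt(exp(s2) - 1)

#' Calibrate field parameters to a target geometric mean and skewness
#'
#' Solves for the total log-scale variance `s2` that gives a lognormal
#' distribution the requested skewness, sets `mu_log = log(geometric_mean)`,
#' and partitions `s2` into three components: iid measurement noise
#' (`measurement_sd_log^2`), a micro-scale nugget, and a spatially
#' structured partial sill (`spatial_frac` of the total). Indoor radon is
#' dominated by building-to-building variability, so most of the variance
#' sits in the nugget and noise components by default, with a short-range
#' structured component carrying the geological signal.
#'
#' @param geometric_mean target geometric mean of point values (Bq/m3,
#'   default 49).
#' @param skew target skewness of the point-value distribution (default
#'   7.84).
#' @param family variogram family for the structured component.
#' @param range range parameter of the structured component in km (default
#'   3, i.e. a practical range of about 9 km for the exponential family).
#' @param spatial_frac fraction of the total log variance that is spatially
#'   structured (default 0.34).
#' @param measurement_sd_log iid measurement noise sd on the log scale
#'   (default 0.45).
#' @return a [field_params()] object.
#' @export
calibrate_field_params <- function(geometric_mean = 49, skew = 7.84,
                                   family = "exponential", range = 3,
                                   spatial_frac = 0.34,
                                   measurement_sd_log = 0.45) {
  stopifnot(geometric_mean > 0, skew > 0, spatial_frac > 0, spatial_frac < 1)
  s2 <- stats::uniroot(function(s2) lognormal_skewness(s2) - skew,
                       interval = c(1e-8, 20), tol = 1e-12)$root
  psill <- spatial_frac * s2
  nugget <- s2 - psill - measurement_sd_log^2
  if (nugget < 0)
    stop("measurement_sd_log^2 + spatial component exceed the total variance implied by the target skewness",
         call. = FALSE)
  field_params(mu_log = log(geometric_mean),
               variogram = variogram_model(family, nugget = nugget,
                                           psill = psill, range = range),
               measurement_sd_log = measurement_sd_log)
}

#' Simulate the latent log-radon field on a grid
#'
#' Draws one realization of a Gaussian random field at the cell centres,
#' with mean `params$mu_log` and covariance `C(h) = sill - gamma(h)` implied
#' by the variogram (the nugget appears as iid cell-level variance). Uses a
#' dense Cholesky factorization, so the grid is limited to 10,000 cells;
#' larger grids are out of scope for this package.
#'
#' @param grid a [grid_spec()].
#' @param params a [field_params()].
#' @param seed integer seed.
#' @return numeric vector of per-cell log-radon values (cell-id order).
#' @export
simulate_log_field <- function(grid, params, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "field_params"))
  nc <- n_cells(grid)
  if (nc > MAX_FIELD_CELLS)
    stop(sprintf("grid has %d cells; dense simulation is limited to %d",
                 nc, MAX_FIELD_CELLS), call. = FALSE)
  vg <- params$variogram
  set.seed(derive_seed(seed, 1000))
  if (sill(vg) <= 0) return(rep(params$mu_log, nc))
  cc <- cell_centers(grid)
  hmat <- as.matrix(stats::dist(cbind(cc$x, cc$y)))
  C <- matrix(vgm_cov(vg, hmat), nc, nc)
  diag(C) <- sill(vg)
  L <- tryCatch(chol(C),
                error = function(e)
                  tryCatch(chol(C + diag(1e-8 * sill(vg), nc)),
                           error = function(e2)
                             stop(sprintf(
                               "covariance not positive definite for variogram (%s, nugget %.4g, psill %.4g, range %.4g)",
                               vg$family, vg$nugget, vg$psill, vg$range),
                               call. = FALSE)))
  as.numeric(params$mu_log + crossprod(L, stats::rnorm(nc)))
}

#' Sample survey measurement points from a simulated field
#'
#' Locations are grid cells drawn uniformly (with replacement by default)
#' with a uniform jitter inside the cell; the measured value is
#' `exp(field[cell] + e)` with `e ~ N(0, measurement_sd_log^2)` iid.
#'
#' @param field per-cell log-radon values from [simulate_log_field()].
#' @param grid the matching [grid_spec()].
#' @param n_points number of survey points (>= 1).
#' @param measurement_sd_log log-scale measurement noise sd (default 0).
#' @param seed integer seed.
#' @param replace sample cells with replacement (default TRUE). Without
#'   replacement `n_points` may not exceed the number of cells.
#' @param jitter place points uniformly within their cell rather than at the
#'   centre (default TRUE).
#' @return a data.frame with columns `x_km`, `y_km`, `cell`, `radon_bqm3`.
#' @export
sample_survey_points <- function(field, grid, n_points,
                                 measurement_sd_log = 0, seed = 1L,
                                 replace = TRUE, jitter = TRUE) {
  stopifnot(inherits(grid, "grid_spec"), length(field) == n_cells(grid),
            is_count(n_points), n_points >= 1, measurement_sd_log >= 0)
  if (!replace && n_points > n_cells(grid))
    stop("n_points exceeds the number of grid cells when sampling without replacement",
         call. = FALSE)
  set.seed(derive_seed(seed, 2000))
  cells <- sample.int(n_cells(grid), n_points, replace = replace)
  cc <- cell_centers(grid)
  off_x <- if (jitter) stats::runif(n_points, -0.5, 0.5) * grid$dx else 0
  off_y <- if (jitter) stats::runif(n_points, -0.5, 0.5) * grid$dy else 0
  noise <- if (measurement_sd_log > 0)
    stats::rnorm(n_points, 0, measurement_sd_log) else 0
  data.frame(x_km = cc$x[cells] + off_x,
             y_km = cc$y[cells] + off_y,
             cell = cells,
             radon_bqm3 = exp(field[cells] + noise))
}
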
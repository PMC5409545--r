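# Ordinary kriging on the log scale, the unbiased lognormal back-transform,
# grid prediction, and aggregation to regions.

# Average duplicated locations (log scale) so the kriging system is
# nonsingular; annual-average semantics make the mean the right summary.
dedupe_points <- function(x, y, values) {
  key <- paste(signif(x, 12), signif(y, 12), sep = "_")
  if (!anyDuplicated(key)) return(list(x = x, y = y, values = values))
  agg <- rowsum(cbind(values, 1), key, reorder = FALSE)
  first <- !duplicated(key)
  list(x = x[first], y = y[first], values = agg[, 1] / agg[, 2])
}

#' Ordinary kriging prediction at one target location
#'
#' Solves the standard ordinary-kriging system in semivariogram form,
#' `[Gamma, 1; 1', 0] [w; mu] = [gamma0; 1]`, where `Gamma[i, j]` is the
#' model semivariance between data points and `gamma0` the semivariances to
#' the target. Returns the BLUP `yhat = sum(w * values)`, the kriging
#' variance `sigma2 = sum(w * gamma0) + mu`, and the Lagrange multiplier
#' `mu` (needed by the lognormal back-transform).
#'
#' Coincident data points are averaged before solving; a still-singular
#' system is an error.
#'
#' @param x,y data point coordinates (km).
#' @param values data values (log scale for lognormal kriging).
#' @param model a [variogram_model()].
#' @param x0,y0 target location.
#' @return a list with `yhat`, `sigma2`, `mu`, `weights`, and the (possibly
#'   deduplicated) data coordinates used.
#' @export
ordinary_kriging <- function(x, y, values, model, x0, y0) {
  stopifnot(length(x) == length(y), length(x) == length(values),
            length(x) >= 1, inherits(model, "variogram_model"),
            is.finite(x0), is.finite(y0))
  p <- dedupe_points(x, y, values)
  k <- length(p$x)
  if (k == 1L) {
    h0 <- sqrt((p$x - x0)^2 + (p$y - y0)^2)
    g0 <- vgm_gamma(model, h0)
    return(list(yhat = p$values, sigma2 = max(2 * g0 - 0, 0), mu = g0,
                weights = 1, x = p$x, y = p$y))
  }
  hmat <- as.matrix(stats::dist(cbind(p$x, p$y)))
  A <- rbind(cbind(matrix(vgm_gamma(model, hmat), k, k), 1),
             c(rep(1, k), 0))
  h0 <- sqrt((p$x - x0)^2 + (p$y - y0)^2)
  g0 <- vgm_gamma(model, h0)
  sol <- tryCatch(solve(A, c(g0, 1)),
                  error = function(e)
                    stop("singular ordinary-kriging system (after averaging duplicates): ",
                         conditionMessage(e), call. = FALSE))
  w <- sol[seq_len(k)]
  mu <- sol[k + 1L]
  sigma2 <- sum(w * g0) + mu
  if (sigma2 < -1e-9)
    warning(sprintf("negative kriging variance %.3g clamped to 0", sigma2))
  list(yhat = sum(w * p$values), sigma2 = max(sigma2, 0), mu = mu,
       weights = w, x = p$x, y = p$y)
}

#' Unbiased back-transform for lognormal ordinary kriging
#'
#' For an ordinary-kriging prediction `yhat` of a log-transformed variable
#' with kriging variance `sigma2` and Lagrange multiplier `mu`, the
#' back-transform `zhat = exp(yhat + sigma2 / 2 - mu)` is unbiased for the
#' original-scale value under the lognormal model; the naive `exp(yhat)`
#' systematically underestimates.
#'
#' @param yhat log-scale kriging estimate(s).
#' @param sigma2 ordinary-kriging variance(s), `>= 0`.
#' @param mu Lagrange multiplier(s) from the same solve.
#' @return back-transformed estimate(s) on the original (Bq/m3) scale.
#' @export
lognormal_backtransform <- function(yhat, sigma2, mu) {
  if (any(!is.finite(yhat)) || any(!is.finite(sigma2)) || any(!is.finite(mu)))
    stop("non-finite input to lognormal_backtransform", call. = FALSE)
  if (any(sigma2 < -1e-9))
    stop("negative kriging variance in lognormal_backtransform", call. = FALSE)
  expo <- yhat + pmax(sigma2, 0) / 2 - mu
  if (any(expo > 700))
    stop("overflow in lognormal back-transform (exponent > 700)", call. = FALSE)
  exp(expo)
}

#' Krige a whole grid from scattered log-scale observations
#'
#' Applies [ordinary_kriging()] at every cell centre using a moving
#' neighborhood of the nearest `k` points (default 16) within a maximum
#' search radius (default three times the model's practical range), then
#' back-transforms with [lognormal_backtransform()]. Cells with no neighbor
#' inside the radius fall back to the global mean of the log data (flagged
#' in the output).
#'
#' @param x,y,values survey locations and log-scale values.
#' @param model a [variogram_model()].
#' @param grid a [grid_spec()].
#' @param n_neighbors nearest-neighbor count (default 16).
#' @param max_radius search radius in km (default `3 * practical_range(model)`).
#' @return a data.frame with one row per cell: `cell`, `x`, `y`, `yhat`,
#'   `sigma2`, `mu`, `zhat`, `fallback`.
#' @export
krige_grid <- function(x, y, values, model, grid, n_neighbors = 16,
                       max_radius = NULL) {
  stopifnot(inherits(grid, "grid_spec"), inherits(model, "variogram_model"))
  p <- dedupe_points(x, y, values)
  if (is.null(max_radius)) max_radius <- 3 * practical_range(model)
  cc <- cell_centers(grid)
  nc <- nrow(cc)
  k <- min(n_neighbors, length(p$x))
  yhat <- sigma2 <- mu <- numeric(nc)
  fallback <- logical(nc)
  gmean <- mean(p$values)
  for (i in seq_len(nc)) {
    d2 <- (p$x - cc$x[i])^2 + (p$y - cc$y[i])^2
    within <- which(d2 <= max_radius^2)
    if (length(within) == 0L) {
      yhat[i] <- gmean
      sigma2[i] <- sill(model)
      mu[i] <- 0
      fallback[i] <- TRUE
      next
    }
    nb <- within[order(d2[within])[seq_len(min(k, length(within)))]]
    ok <- ordinary_kriging(p$x[nb], p$y[nb], p$values[nb], model,
                           cc$x[i], cc$y[i])
    yhat[i] <- ok$yhat; sigma2[i] <- ok$sigma2; mu[i] <- ok$mu
  }
  if (any(fallback))
    message(sprintf("krige_grid: %d of %d cells had no neighbor within %.3g km; global-mean fallback used",
                    sum(fallback), nc, max_radius))
  data.frame(cell = cc$cell, x = cc$x, y = cc$y,
             yhat = yhat, sigma2 = sigma2, mu = mu,
             zhat = lognormal_backtransform(yhat, sigma2, mu),
             fallback = fallback)
}

#' Aggregate a kriged field to region-level mean concentrations
#'
#' Unweighted arithmetic mean of the back-transformed cell values within
#' each region; cells are equal-area, so this equals the area-weighted mean.
#'
#' @param kriged the data.frame from [krige_grid()] (or any with `cell`,
#'   `zhat`).
#' @param regions a `region_map` from [make_regions()].
#' @return a data.frame with `region`, `radon`, `n_cells`.
#' @export
aggregate_to_regions <- function(kriged, regions) {
  stopifnot(inherits(regions, "region_map"))
  memb <- regions$membership
  if (length(memb) != nrow(kriged))
    stop("region membership does not match kriged grid size", call. = FALSE)
  counts <- tabulate(memb, nbins = regions$n_regions)
  if (any(counts == 0))
    stop("region(s) with no grid cells: ",
         paste(which(counts == 0), collapse = ", "), call. = FALSE)
  sums <- as.numeric(rowsum(kriged$zhat, memb))
  data.frame(region = sort(unique(memb)), radon = sums / counts,
             n_cells = counts)
}
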
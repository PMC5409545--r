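# Empirical semivariogram estimation and parametric model fitting on the
# log-radon scale.

#' Adjusted Fisher--Pearson sample skewness
#'
#' The bias-adjusted coefficient `g1 * sqrt(n (n - 1)) / (n - 2)`, where
#' `g1 = m3 / m2^(3/2)` is the method-of-moments skewness. This is the form
#' most statistical software reports and the one used to diagnose the strong
#' right skew of indoor radon measurements.
#'
#' @param x numeric vector, length at least 3, non-constant.
#' @return the skewness coefficient.
#' @export
skewness <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("skewness requires at least 3 observations", call. = FALSE)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) stop("skewness undefined for zero-variance input", call. = FALSE)
  g1 <- mean(xc^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Empirical semivariogram of scattered observations
#'
#' Classical (Matheron) estimator: for each lag bin `k`,
#' `gamma(h_k) = sum over pairs in bin of (y_i - y_j)^2 / (2 N_k)`.
#' Bins are equal-width on (0, max_lag]; pairs at exactly zero separation
#' (duplicate locations) are tallied separately in the `n_zero` attribute and
#' never enter a positive-lag bin. Empty bins are kept with `NA`
#' semivariance and a zero pair count rather than interpolated.
#'
#' @param x,y point coordinates (km).
#' @param values observed values at the points (log scale for radon work).
#' @param n_lags number of lag bins (default 15).
#' @param max_lag largest separation considered; default half the diagonal of
#'   the bounding box of the points.
#' @return a data.frame of class `empirical_variogram` with columns
#'   `lag` (bin centre), `gamma` and `n_pairs`.
#' @export
empirical_semivariogram <- function(x, y, values, n_lags = 15, max_lag = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(values))
  n <- length(x)
  if (n < 2) stop("need at least 2 points for a semivariogram", call. = FALSE)
  d <- as.numeric(stats::dist(cbind(x, y)))
  if (is.null(max_lag)) {
    max_lag <- sqrt(diff(range(x))^2 + diff(range(y))^2) / 2
  }
  if (!is.numeric(max_lag) || max_lag <= 0)
    stop("max_lag must be positive", call. = FALSE)
  dv <- as.numeric(stats::dist(values))^2
  zero <- d <= .Machine$double.eps
  keep <- !zero & d <= max_lag
  if (!any(keep))
    stop("all point pairs lie beyond max_lag; increase max_lag", call. = FALSE)
  breaks <- seq(0, max_lag, length.out = n_lags + 1L)
  bin <- findInterval(d[keep], breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  npairs <- tabulate(bin, nbins = n_lags)
  ssq <- vapply(seq_len(n_lags),
                function(k) sum(dv[keep][bin == k]), numeric(1))
  gamma <- ifelse(npairs > 0, ssq / (2 * npairs), NA_real_)
  out <- data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    gamma = gamma, n_pairs = npairs)
  attr(out, "n_zero") <- sum(zero)
  attr(out, "gamma_zero") <- if (any(zero)) sum(dv[zero]) / (2 * sum(zero)) else NA_real_
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Parametric semivariogram model
#'
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget nugget `c0 >= 0` (discontinuity at the origin).
#' @param psill partial sill `c >= 0`; total sill is `nugget + psill`.
#' @param range range parameter `a > 0` (km). For the spherical family this
#'   is the distance at which the sill is reached; for the exponential and
#'   gaussian families the practical range is `3 a` and `sqrt(3) a`.
#' @return an object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(is.numeric(nugget), nugget >= 0,
            is.numeric(psill), psill >= 0,
            is.numeric(range), range > 0)
  structure(list(family = family, nugget = as.numeric(nugget),
                 psill = as.numeric(psill), range = as.numeric(range)),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, nugget %.4g, partial sill %.4g, range %.4g km (sill %.4g)\n",
              x$family, x$nugget, x$psill, x$range, x$nugget + x$psill))
  invisible(x)
}

#' Total sill of a variogram model
#' @param model a [variogram_model()].
#' @export
sill <- function(model) model$nugget + model$psill

#' Practical range of a variogram model
#'
#' Distance at which the model reaches (approximately) its sill: `a` for the
#' spherical family, `3 a` exponential, `sqrt(3) a` gaussian.
#' @param model a [variogram_model()].
#' @export
practical_range <- function(model) {
  switch(model$family,
         spherical = model$range,
         exponential = 3 * model$range,
         gaussian = sqrt(3) * model$range)
}

#' Evaluate a semivariogram model
#'
#' `gamma(0) = 0` by convention; the nugget is the limit from the right.
#'
#' @param model a [variogram_model()].
#' @param h vector of separation distances (km), `>= 0`.
#' @return semivariance at each `h`.
#' @export
vgm_gamma <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"), all(h >= 0))
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  g <- switch(model$family,
    spherical = ifelse(h >= a, 1, 1.5 * (h / a) - 0.5 * (h / a)^3),
    exponential = 1 - exp(-h / a),
    gaussian = 1 - exp(-(h / a)^2))
  out <- c0 + c1 * g
  out[h == 0] <- 0
  out
}

# Covariance implied by a variogram model: C(h) = sill - gamma(h), with
# C(0) = sill (the nugget reappears as white noise on the diagonal).
vgm_cov <- function(model, h) sill(model) - vgm_gamma(model, h)

#' Fit a semivariogram model by Cressie-weighted least squares
#'
#' Minimizes `sum_k N_k * (gamma_hat_k / gamma_model_k - 1)^2`, the
#' Cressie (weights `N_k / gamma_model^2`) criterion, over
#' `(nugget, psill, range)` with box constraints `c0 >= 0`, `c >= 0`,
#' `a > 0`. Optimization runs L-BFGS-B from several data-driven starts and
#' polishes the best solution with Nelder--Mead.
#'
#' @param emp an [empirical_semivariogram()] result.
#' @param family model family passed to [variogram_model()].
#' @return the fitted [variogram_model()], with attributes `objective` and
#'   `converged`.
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian")) {
  family <- match.arg(family)
  ok <- !is.na(emp$gamma) & emp$n_pairs > 0
  if (sum(ok) < 3)
    stop("need at least 3 nonempty lag bins to fit a variogram", call. = FALSE)
  h <- emp$lag[ok]; g <- emp$gamma[ok]; w <- emp$n_pairs[ok]

  obj <- function(par) {
    m <- variogram_model(family, nugget = par[1], psill = par[2], range = par[3])
    gm <- vgm_gamma(m, h)
    gm <- pmax(gm, 1e-12)
    sum(w * (g / gm - 1)^2)
  }
  gmax <- max(g); hmax <- max(h)
  i95 <- which(g >= 0.95 * gmax)[1]
  starts <- list(
    c(max(g[1] * 0.5, 1e-6), max(gmax - g[1] * 0.5, 1e-6), max(h[i95], hmax / 4)),
    c(1e-6, gmax, hmax / 3),
    c(gmax * 0.5, gmax * 0.5, hmax / 2),
    c(gmax * 0.9, gmax * 0.1, hmax / 2))  # near-pure-nugget start
  lower <- c(0, 0, hmax * 1e-4)
  upper <- c(gmax * 4 + 1e-6, gmax * 4 + 1e-6, hmax * 10)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("variogram fit failed to converge from all starts", call. = FALSE)
  }
  # Nelder-Mead polish on a log-ish parameterization is unnecessary here;
  # a bounded polish from the best iterate tightens the optimum instead.
  polish <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 1000, factr = 1)),
    error = function(e) best)
  if (polish$value <= best$value) best <- polish
  nm <- tryCatch(
    stats::optim(best$par, function(p) {
      p <- pmin(pmax(p, lower), upper); obj(p)
    }, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) best)
  if (nm$value <= best$value) {
    nm$par <- pmin(pmax(nm$par, lower), upper)
    best <- nm
  }
  if (!is.finite(best$value)) {
    cond <- structure(
      class = c("variogram_fit_error", "error", "condition"),
      list(message = "variogram fit did not reach a finite optimum",
           call = sys.call(-1), best = best))
    stop(cond)
  }
  out <- variogram_model(family, nugget = best$par[1], psill = best$par[2],
                         range = best$par[3])
  attr(out, "objective") <- best$value
  attr(out, "converged") <- TRUE
  out
}
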
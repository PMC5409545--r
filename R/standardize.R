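# Indirect standardization: pooled reference rates, expected counts, and
# standardized incidence ratios per region.

strata_key <- function(sex, age_group) paste(sex, age_group, sep = ":")

#' Restrict a strata table by sex and maximum age
#'
#' Age filtering keeps the 5-year groups entirely below the cut (e.g.
#' `max_age = 19` keeps 0-4 through 15-19), matching analyses restricted to
#' children and adolescents.
#'
#' @param strata a strata data.frame (`region`, `sex`, `age_group`,
#'   `population`, `observed`).
#' @param sex optional `"male"` or `"female"`.
#' @param max_age optional upper age bound.
#' @return the filtered strata data.frame.
#' @export
filter_strata <- function(strata, sex = NULL, max_age = NULL) {
  out <- strata
  if (!is.null(sex)) {
    stopifnot(sex %in% c("male", "female"))
    out <- out[out$sex == sex, , drop = FALSE]
  }
  if (!is.null(max_age)) {
    b <- age_group_bounds(out$age_group)
    out <- out[b[, "upper"] <= max_age, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no strata left after filtering", call. = FALSE)
  out
}

#' Pooled (internal) reference rates from a strata table
#'
#' Indirect standardization with internally derived rates:
#' `rate(s, a) = sum_r observed(r, s, a) / sum_r population(r, s, a)`.
#'
#' @param strata a strata data.frame.
#' @return a data.frame with `sex`, `age_group`, `rate`.
#' @export
reference_rates_from_pooled <- function(strata) {
  key <- strata_key(strata$sex, strata$age_group)
  pop <- rowsum(strata$population, key)
  obs <- rowsum(strata$observed, key)
  if (any(pop[, 1] <= 0))
    stop("zero pooled population in stratum ",
         paste(rownames(pop)[pop[, 1] <= 0], collapse = ", "), call. = FALSE)
  parts <- strsplit(rownames(pop), ":", fixed = TRUE)
  data.frame(sex = vapply(parts, `[`, "", 1),
             age_group = vapply(parts, `[`, "", 2),
             rate = as.numeric(obs[, 1] / pop[, 1]),
             row.names = NULL)
}

#' Expected counts per region by indirect standardization
#'
#' `E_r = sum over (sex, age) of population(r, s, a) * rate(s, a)`.
#'
#' @param strata a strata data.frame.
#' @param rates reference rates (`sex`, `age_group`, `rate`), e.g. from
#'   [reference_rates_from_pooled()].
#' @return a data.frame with `region`, `expected`.
#' @export
expected_counts <- function(strata, rates) {
  r <- rates$rate[match(strata_key(strata$sex, strata$age_group),
                        strata_key(rates$sex, rates$age_group))]
  if (anyNA(r))
    stop("rates missing for strata present in the table", call. = FALSE)
  e <- rowsum(strata$population * r, strata$region)
  data.frame(region = as.integer(rownames(e)), expected = as.numeric(e[, 1]))
}

#' Standardized incidence ratios
#'
#' `SIR_r = O_r / E_r` with `E_r > 0` required.
#'
#' @param observed observed counts per region.
#' @param expected expected counts per region (positive).
#' @param region optional region ids (default `seq_along(observed)`).
#' @return a data.frame with `region`, `observed`, `expected`, `sir`.
#' @export
sir <- function(observed, expected, region = seq_along(observed)) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0))
    stop("expected counts must be positive to form an SIR", call. = FALSE)
  if (any(observed < 0)) stop("negative observed counts", call. = FALSE)
  data.frame(region = region, observed = observed, expected = expected,
             sir = observed / expected)
}

#' Region-level observed, expected and SIR from a strata table
#'
#' Convenience wrapper: filters by sex / maximum age, derives pooled
#' internal reference rates (unless external rates are given), computes
#' expected counts and the SIR per region.
#'
#' @inheritParams filter_strata
#' @param rates optional external reference rates; default internal pooled.
#' @return a data.frame with `region`, `observed`, `expected`, `sir`.
#' @export
compute_sir <- function(strata, sex = NULL, max_age = NULL, rates = NULL) {
  st <- filter_strata(strata, sex = sex, max_age = max_age)
  if (is.null(rates)) rates <- reference_rates_from_pooled(st)
  e <- expected_counts(st, rates)
  o <- rowsum(st$observed, st$region)
  obs <- data.frame(region = as.integer(rownames(o)),
                    observed = as.numeric(o[, 1]))
  m <- merge(obs, e, by = "region")
  m <- m[order(m$region), , drop = FALSE]
  sir(m$observed, m$expected, region = m$region)
}
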
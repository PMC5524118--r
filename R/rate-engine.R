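#' Convert event counts to stratum rates per 100 000
#'
#' Joins combined event totals to the population-denominator table and scales
#' to rates per 100 000 person-years; SDs scale the same way, giving the
#' rate SE. A zero count yields a zero rate (and, under the default variance
#' model, zero SE).
#'
#' @param counts Data frame with `year`, `sex`, `age_group`, `count`, `sd`
#'   (see [combine_sources()]).
#' @param population Data frame with `year`, `sex`, `age_group`,
#'   `population`; a row must exist for every count row.
#' @return Data frame with columns `year`, `sex`, `age_group`, `rate`, `se`,
#'   `count`, `sd`, `population`.
#' @examples
#' cnt <- data.frame(year = 2011, sex = "men", age_group = "45-64",
#'                   count = 10000, sd = 300)
#' pop <- data.frame(year = 2011, sex = "men", age_group = "45-64",
#'                   population = 1e6)
#' compute_rates(cnt, pop)$rate  # 1000
#' @export
compute_rates <- function(counts, population) {
  stopifnot(is.data.frame(counts), is.data.frame(population))
  keys <- c("year", "sex", "age_group")
  out <- merge(counts, population[, c(keys, "population")], by = keys,
               all.x = TRUE, sort = TRUE)
  if (anyNA(out$population)) {
    miss <- out[is.na(out$population), keys][1, ]
    stop(sprintf("no population row for year %s, %s %s",
                 miss$year, miss$sex, miss$age_group), call. = FALSE)
  }
  if (any(out$population <= 0)) {
    stop("populations must be positive", call. = FALSE)
  }
  out$rate <- 1e5 * out$count / out$population
  out$se <- 1e5 * out$sd / out$population
  out <- out[do.call(order, out[keys]),
             c(keys, "rate", "se", "count", "sd", "population")]
  rownames(out) <- NULL
  out
}

#' Standard population age weights
#'
#' Age-distribution weights for direct standardization. The default
#' approximates the 2010 US Decennial Census distribution of adults aged 18
#' and over across the four surveillance age groups.
#'
#' @param weights Named non-negative numeric vector over the age groups,
#'   summing to 1.
#' @return Named numeric vector of weights.
#' @export
standard_population <- function(weights = c("18-44" = 0.481, "45-64" = 0.347,
                                            "65-74" = 0.093, "75+" = 0.079)) {
  if (any(weights < 0)) {
    stop("standard-population weights must be non-negative", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("standard-population weights must sum to 1", call. = FALSE)
  }
  weights
}

#' Direct age standardization of stratum rates
#'
#' Computes the directly age-standardized rate for each year and scope
#' (`overall`, `men`, `women`): the weighted mean of the age-specific rates
#' with fixed standard-population weights. For the `overall` scope, sexes are
#' first pooled within each age group (counts and populations summed; count
#' variances added). The variance of the standardized rate is
#' `sum(weight^2 * se^2)` — age groups are treated as independent — and the
#' 95% CI is the normal approximation `rate +/- 1.96 * sqrt(variance)`.
#'
#' @param rates Data frame from [compute_rates()] (needs `year`, `sex`,
#'   `age_group`, `rate`, `se`; for the `overall` scope also `count`, `sd`,
#'   `population`).
#' @param std Standard-population weights, see [standard_population()]. The
#'   names of this vector define the age groups that must be present.
#' @param scopes Character vector among `"overall"`, `"men"`, `"women"`.
#' @return Data frame with `year`, `scope`, `rate`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
age_standardize <- function(rates, std = standard_population(),
                            scopes = c("overall", "men", "women")) {
  stopifnot(is.data.frame(rates))
  scopes <- match.arg(scopes, several.ok = TRUE)
  groups <- names(std)
  out <- list()
  for (scope in scopes) {
    if (scope == "overall") {
      need <- c("count", "sd", "population")
      if (!all(need %in% names(rates))) {
        stop("overall standardization needs count, sd and population columns",
             call. = FALSE)
      }
      counts <- stats::aggregate(rates[c("count", "population")],
                                 rates[c("year", "age_group")], sum)
      vars <- stats::aggregate(list(var = rates$sd^2),
                               rates[c("year", "age_group")], sum)
      d <- merge(counts, vars, by = c("year", "age_group"))
      d$rate <- 1e5 * d$count / d$population
      d$se <- 1e5 * sqrt(d$var) / d$population
    } else {
      d <- rates[rates$sex == scope, ]
    }
    for (y in sort(unique(d$year))) {
      dy <- d[d$year == y, ]
      if (!all(groups %in% dy$age_group)) {
        stop(sprintf("missing age group(s) for %s in %s: %s", scope, y,
                     paste(setdiff(groups, dy$age_group), collapse = ", ")),
             call. = FALSE)
      }
      dy <- dy[match(groups, dy$age_group), ]
      r <- sum(std * dy$rate)
      v <- sum(std^2 * dy$se^2)
      out[[length(out) + 1L]] <- data.frame(
        year = y, scope = scope, rate = r, se = sqrt(v),
        ci_low = r - 1.96 * sqrt(v), ci_high = r + 1.96 * sqrt(v),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative percent change between two rates
#'
#' `100 * (rate_end - rate_start) / rate_start`; negative values are
#' declines. Reported to one decimal in rendered tables; the function returns
#' full precision.
#'
#' @param rate_start,rate_end Rates on the same scale; `rate_start` must be
#'   positive.
#' @return Percent change (numeric).
#' @examples
#' relative_change(1296.8, 1170.3)  # -9.8 (to one decimal)
#' @export
relative_change <- function(rate_start, rate_end) {
  if (any(rate_start <= 0)) {
    stop("relative change is undefined for a non-positive start rate",
         call. = FALSE)
  }
  100 * (rate_end - rate_start) / rate_start
}

#' Percent share of a part in a whole
#'
#' @param part,whole Non-negative counts with `part <= whole`, `whole > 0`.
#' @return `100 * part / whole` (numeric, full precision).
#' @examples
#' category_share(2099874, 2829161)  # 74.2 (to one decimal)
#' @export
category_share <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be positive", call. = FALSE)
  if (any(part < 0) || any(part > whole)) {
    stop("part must lie in [0, whole]", call. = FALSE)
  }
  100 * part / whole
}
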
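#' Deterministic counterfactual baseline rates
#'
#' Projects a fitted stratum trend into post-anchor years under one of the
#' two counterfactual strategies: `"stable"` holds the modeled anchor-year
#' rate constant; `"trend"` compounds it year-on-year by the fitted APC.
#' Projection years must follow the anchor year.
#'
#' @param fit An [apc_fit()] or [apc_summary_fit()] object.
#' @param strategy `"stable"` or `"trend"`.
#' @param years Projection years, all strictly after the anchor year.
#' @return Numeric vector of rates per 100 000, named by year.
#' @examples
#' fit <- apc_summary_fit(anchor_rate = 152.9, apc = -2.1, anchor = 2011)
#' round(project_baseline(fit, "trend", 2012:2013), 1)  # 149.7 146.5
#' @export
project_baseline <- function(fit, strategy = c("stable", "trend"), years) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(fit, "apc_fit"))
  if (any(years <= fit$anchor)) {
    stop(sprintf("projection years must follow the anchor year (%d)",
                 fit$anchor), call. = FALSE)
  }
  predict(fit, years = years, strategy = strategy)
}

#' Simulated counterfactual baseline with Monte Carlo uncertainty
#'
#' Runs [simulate.apc_fit()] (`n_sims` replicates; anchor rate and — for the
#' trend strategy — APC drawn from their sampling distributions, one draw per
#' replicate compounded across years) and summarizes each projection year by
#' the mean and SD of the simulated rates.
#'
#' @inheritParams project_baseline
#' @param n_sims Number of Monte Carlo replicates (>= 2; default 1000).
#' @param seed Integer seed for reproducibility.
#' @param keep_draws If `TRUE`, the draw matrix is attached as attribute
#'   `"draws"` (needed for covariance-aware aggregation across years).
#' @param distribution Draw scale, see [simulate.apc_fit()].
#' @return Data frame with columns `strategy`, `year`, `rate_mean`,
#'   `rate_sd`, `n_sims`.
#' @export
simulate_baseline <- function(fit, strategy = c("stable", "trend"), years,
                              n_sims = 1000, seed = NULL, keep_draws = FALSE,
                              distribution = c("normal", "lognormal")) {
  strategy <- match.arg(strategy)
  distribution <- match.arg(distribution)
  stopifnot(inherits(fit, "apc_fit"))
  if (any(years <= fit$anchor)) {
    stop(sprintf("projection years must follow the anchor year (%d)",
                 fit$anchor), call. = FALSE)
  }
  draws <- stats::simulate(fit, nsim = n_sims, seed = seed, years = years,
                           strategy = strategy, distribution = distribution)
  out <- data.frame(
    strategy = strategy, year = years,
    rate_mean = rowMeans(draws),
    rate_sd = apply(draws, 1L, stats::sd),
    n_sims = n_sims, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (keep_draws) attr(out, "draws") <- draws
  out
}

#' Convert projected rates into expected event counts
#'
#' `events = rate_mean * population / 1e5` per year, with a normal 95% CI
#' from the simulated rate SD: `events +/- 1.96 * rate_sd * population / 1e5`.
#'
#' @param projection Data frame from [simulate_baseline()] (columns `year`,
#'   `rate_mean`, `rate_sd`; a `"draws"` attribute, if present, is carried
#'   through on the events scale).
#' @param population Either a data frame with `year` and `population`
#'   columns or a numeric vector named by year; a value must exist for every
#'   projection year.
#' @return `projection` with columns `events_mean`, `events_sd`,
#'   `events_lo`, `events_hi` added.
#' @export
expected_events <- function(projection, population) {
  stopifnot(is.data.frame(projection),
            all(c("year", "rate_mean", "rate_sd") %in% names(projection)))
  if (is.data.frame(population)) {
    pop <- population$population[match(projection$year, population$year)]
  } else {
    pop <- population[as.character(projection$year)]
  }
  if (anyNA(pop)) {
    stop("missing population for projection year(s): ",
         paste(projection$year[is.na(pop)], collapse = ", "), call. = FALSE)
  }
  scale <- pop / 1e5
  out <- projection
  out$events_mean <- out$rate_mean * scale
  out$events_sd <- out$rate_sd * scale
  out$events_lo <- out$events_mean - 1.96 * out$events_sd
  out$events_hi <- out$events_mean + 1.96 * out$events_sd
  draws <- attr(projection, "draws")
  if (!is.null(draws)) {
    attr(out, "draws") <- draws * scale  # recycles by row (years)
  }
  out
}
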
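#' Inverse-variance-weighted log-linear trend fit (annual percent change)
#'
#' Fits `ln(rate) = a + b * (year - anchor)` by weighted least squares with
#' weights equal to the inverse variance of each log rate,
#' `w = 1 / var(ln rate) = (rate / se)^2` (delta method). The slope `b`
#' translates into the annual percent change, `APC = 100 * (exp(b) - 1)`;
#' because the design is centered on the anchor year, the intercept `a` is
#' the modeled log rate in the anchor year, so `exp(a)` is the modeled anchor
#' rate whose SE follows by the delta method. Standard errors are the
#' known-variance (meta-analytic) WLS errors, i.e. the square roots of the
#' diagonal of `(X' W X)^(-1)`; all inference uses the standard normal
#' reference distribution.
#'
#' @param formula A formula `rate ~ year`.
#' @param data Data frame containing the variables of `formula` and, unless
#'   `se` is given explicitly, a column named `se` with the rate SEs.
#' @param se Rate standard errors: a column name in `data` or a numeric
#'   vector. Units of the rate.
#' @param window Optional vector of years to restrict the fit to (e.g.
#'   `2006:2011`).
#' @param anchor Anchor year at which the modeled rate is extracted; defaults
#'   to the last year in the fit window.
#' @param label Optional label for printing (e.g. `"men 65-74"`).
#' @return An object of class `apc_fit` with components `coefficients`
#'   (`log_rate_anchor`, `slope`), `vcov`, `apc`, `apc_se`, `apc_ci`,
#'   `p_value`, `anchor`, `anchor_rate`, `anchor_rate_se`, `model` (the data
#'   used), `n`, `label`.
#' @examples
#' d <- data.frame(year = 2006:2011, rate = 100 * 0.98^(0:5), se = 1)
#' fit <- apc_fit(rate ~ year, d, anchor = 2011)
#' coef(fit)
#' fit$apc  # -2
#' @seealso [predict.apc_fit()], [simulate.apc_fit()], [compare_apc()],
#'   [fit_trends()]
#' @export
apc_fit <- function(formula, data, se = "se", window = NULL, anchor = NULL,
                    label = NULL) {
  mf <- stats::model.frame(formula, data)
  rate <- mf[[1L]]
  year <- mf[[2L]]
  if (is.character(se)) {
    if (!se %in% names(data)) {
      stop(sprintf("no column '%s' in 'data' for the rate SEs", se),
           call. = FALSE)
    }
    se <- data[[se]]
  }
  se <- as.numeric(se)
  if (length(se) == 1L) se <- rep(se, length(rate))
  if (length(se) != length(rate)) {
    stop("'se' must have one value per rate", call. = FALSE)
  }
  if (!is.null(window)) {
    keep <- year %in% window
    rate <- rate[keep]; year <- year[keep]; se <- se[keep]
  }
  ord <- order(year)
  rate <- rate[ord]; year <- year[ord]; se <- se[ord]
  if (length(rate) < 3L) {
    stop("at least 3 years of rates are required to fit a trend",
         call. = FALSE)
  }
  if (any(rate <= 0)) {
    stop("all rates must be positive to fit a log-linear trend",
         call. = FALSE)
  }
  if (any(se <= 0)) {
    stop("all rate SEs must be positive (they define the weights)",
         call. = FALSE)
  }
  if (is.null(anchor)) anchor <- max(year)

  x <- year - anchor
  y <- log(rate)
  w <- (rate / se)^2            # 1 / var(ln rate), delta method

  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0) stop("years are collinear; cannot fit a trend", call. = FALSE)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar

  # known-variance WLS covariance: (X'WX)^-1
  vcov <- matrix(c(1 / sw + xbar^2 / sxx, -xbar / sxx,
                   -xbar / sxx, 1 / sxx), 2L, 2L,
                 dimnames = list(c("log_rate_anchor", "slope"),
                                 c("log_rate_anchor", "slope")))
  slope_se <- sqrt(vcov["slope", "slope"])
  int_se <- sqrt(vcov["log_rate_anchor", "log_rate_anchor"])

  apc <- 100 * (exp(slope) - 1)
  apc_se <- 100 * exp(slope) * slope_se
  apc_ci <- 100 * (exp(slope + c(-1, 1) * 1.96 * slope_se) - 1)
  z <- slope / slope_se
  p_value <- 2 * stats::pnorm(-abs(z))

  anchor_rate <- exp(intercept)
  anchor_rate_se <- anchor_rate * int_se

  fit <- list(
    coefficients = c(log_rate_anchor = intercept, slope = slope),
    vcov = vcov, slope_se = slope_se,
    apc = apc, apc_se = apc_se, apc_ci = apc_ci,
    z = z, p_value = p_value,
    anchor = anchor, anchor_rate = anchor_rate,
    anchor_rate_se = anchor_rate_se,
    model = data.frame(year = year, rate = rate, se = se, weight = w,
                       fitted = exp(intercept + slope * x)),
    n = length(rate), label = label,
    call = match.call()
  )
  class(fit) <- "apc_fit"
  fit
}

#' Construct a trend object from published summary estimates
#'
#' Builds an `apc_fit`-compatible object directly from a reported modeled
#' anchor rate and APC (with optional SEs), so published estimates can be
#' projected and simulated exactly like a freshly fitted model.
#'
#' @param anchor_rate Modeled rate per 100 000 in the anchor year.
#' @param apc Annual percent change, in percent per year.
#' @param anchor Anchor year.
#' @param anchor_rate_se,apc_se Standard errors (0 gives deterministic
#'   projections).
#' @param label Optional label.
#' @return An object of class `apc_fit` (without a `model` data component).
#' @examples
#' fit <- apc_summary_fit(anchor_rate = 152.9, apc = -2.1, anchor = 2011)
#' predict(fit, years = 2012)  # 149.7 per 100 000 (one decimal)
#' @export
apc_summary_fit <- function(anchor_rate, apc, anchor, anchor_rate_se = 0,
                            apc_se = 0, label = NULL) {
  stopifnot(anchor_rate > 0, apc > -100, anchor_rate_se >= 0, apc_se >= 0)
  slope <- log(1 + apc / 100)
  growth <- 1 + apc / 100
  slope_se <- if (apc_se > 0) apc_se / (100 * growth) else 0
  int_se <- if (anchor_rate_se > 0) anchor_rate_se / anchor_rate else 0
  vcov <- matrix(c(int_se^2, 0, 0, slope_se^2), 2L, 2L,
                 dimnames = list(c("log_rate_anchor", "slope"),
                                 c("log_rate_anchor", "slope")))
  z <- if (slope_se > 0) slope / slope_se else ifelse(slope == 0, 0, Inf * sign(slope))
  fit <- list(
    coefficients = c(log_rate_anchor = log(anchor_rate), slope = slope),
    vcov = vcov, slope_se = slope_se,
    apc = apc, apc_se = apc_se,
    apc_ci = 100 * (exp(slope + c(-1, 1) * 1.96 * slope_se) - 1),
    z = z, p_value = 2 * stats::pnorm(-abs(z)),
    anchor = anchor, anchor_rate = anchor_rate,
    anchor_rate_se = anchor_rate_se,
    model = NULL, n = NA_integer_, label = label, call = match.call()
  )
  class(fit) <- "apc_fit"
  fit
}

#' @export
coef.apc_fit <- function(object, ...) object$coefficients

#' @export
vcov.apc_fit <- function(object, ...) object$vcov

#' @export
confint.apc_fit <- function(object, parm = c("apc", "slope"), level = 0.95, ...) {
  parm <- match.arg(parm)
  q <- stats::qnorm(1 - (1 - level) / 2)
  if (parm == "slope") {
    s <- object$coefficients[["slope"]]
    out <- s + c(-1, 1) * q * object$slope_se
  } else {
    s <- object$coefficients[["slope"]]
    out <- 100 * (exp(s + c(-1, 1) * q * object$slope_se) - 1)
  }
  names(out) <- c(sprintf("%.1f %%", 100 * (1 - level) / 2),
                  sprintf("%.1f %%", 100 * (1 - (1 - level) / 2)))
  out
}

#' @export
fitted.apc_fit <- function(object, ...) {
  if (is.null(object$model)) stop("no data component in this fit", call. = FALSE)
  object$model$fitted
}

#' @export
residuals.apc_fit <- function(object, type = c("working", "pearson"), ...) {
  type <- match.arg(type)
  if (is.null(object$model)) stop("no data component in this fit", call. = FALSE)
  r <- log(object$model$rate) - log(object$model$fitted)
  if (type == "pearson") r <- r * sqrt(object$model$weight)
  r
}

#' Deterministic rate projection from a trend fit
#'
#' Under the `"trend"` strategy the modeled anchor rate is compounded
#' year-on-year by the fitted APC:
#' `rate(y) = anchor_rate * (1 + apc/100)^(y - anchor)`. Under `"stable"`
#' the anchor rate is held constant.
#'
#' @param object An [apc_fit()] (or [apc_summary_fit()]) object.
#' @param years Years to predict at (any years for `"trend"`; the in-window
#'   fitted curve is the same expression).
#' @param strategy `"trend"` (default) or `"stable"`.
#' @param se.fit If `TRUE`, also return delta-method SEs of the projected
#'   rate (for `"trend"` these use the full coefficient covariance).
#' @param ... Unused.
#' @return Numeric vector of rates (named by year), or a list with `fit` and
#'   `se.fit`.
#' @export
predict.apc_fit <- function(object, years, strategy = c("trend", "stable"),
                            se.fit = FALSE, ...) {
  strategy <- match.arg(strategy)
  x <- years - object$anchor
  b <- object$coefficients
  if (strategy == "trend") {
    rate <- exp(b[["log_rate_anchor"]] + b[["slope"]] * x)
    if (se.fit) {
      v <- object$vcov
      var_log <- v[1, 1] + x^2 * v[2, 2] + 2 * x * v[1, 2]
      return(list(fit = stats::setNames(rate, years),
                  se.fit = stats::setNames(rate * sqrt(var_log), years)))
    }
  } else {
    rate <- rep(object$anchor_rate, length(years))
    if (se.fit) {
      return(list(fit = stats::setNames(rate, years),
                  se.fit = stats::setNames(rep(object$anchor_rate_se,
                                               length(years)), years)))
    }
  }
  stats::setNames(rate, years)
}

#' Monte Carlo simulation of baseline rate trajectories
#'
#' Propagates the uncertainty of a trend fit into projected rates: each
#' replicate draws the anchor rate from `Normal(anchor_rate,
#' anchor_rate_se)` truncated at 0 and — for the `"trend"` strategy — a
#' single APC from `Normal(apc, apc_se)`, then projects deterministically
#' across all requested years (the same APC draw compounds year-on-year
#' within a replicate). With `distribution = "lognormal"` the draws are made
#' on the log scale for both coefficients instead.
#'
#' @param object An [apc_fit()] object.
#' @param nsim Number of replicates (default 1000).
#' @param seed Optional integer seed.
#' @param years Years to project.
#' @param strategy `"stable"` or `"trend"`.
#' @param distribution Sampling scale of the draws.
#' @param ... Unused.
#' @return A numeric matrix with `length(years)` rows (named by year) and
#'   `nsim` columns of simulated rates.
#' @export
simulate.apc_fit <- function(object, nsim = 1000, seed = NULL, years,
                             strategy = c("trend", "stable"),
                             distribution = c("normal", "lognormal"), ...) {
  strategy <- match.arg(strategy)
  distribution <- match.arg(distribution)
  stopifnot(nsim >= 2)
  if (!is.null(seed)) set.seed(seed)
  x <- years - object$anchor

  rtrunc_norm <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out <= 0)
    while (length(bad)) {
      out[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[out[bad] <= 0]
    }
    out
  }

  if (distribution == "normal") {
    anchor_draw <- rtrunc_norm(nsim, object$anchor_rate, object$anchor_rate_se)
    growth <- if (strategy == "trend") {
      1 + stats::rnorm(nsim, object$apc, object$apc_se) / 100
    } else rep(1, nsim)
  } else {
    b <- object$coefficients
    int_se <- if (object$anchor_rate > 0) object$anchor_rate_se / object$anchor_rate else 0
    anchor_draw <- exp(stats::rnorm(nsim, b[["log_rate_anchor"]], int_se))
    growth <- if (strategy == "trend") {
      exp(stats::rnorm(nsim, b[["slope"]], object$slope_se))
    } else rep(1, nsim)
  }
  out <- outer(x, seq_len(nsim), function(xx, j) anchor_draw[j] * growth[j]^xx)
  rownames(out) <- as.character(years)
  out
}

#' Compare two annual percent changes
#'
#' Two-sided normal test of equality of the log-linear slopes of two
#' independent trend fits: `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param fit_a,fit_b [apc_fit()] objects fitted on disjoint data.
#' @return List with `slope_diff`, `se`, `z`, `p_value`.
#' @export
compare_apc <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "apc_fit"), inherits(fit_b, "apc_fit"))
  d <- fit_a$coefficients[["slope"]] - fit_b$coefficients[["slope"]]
  se <- sqrt(fit_a$slope_se^2 + fit_b$slope_se^2)
  z <- if (se > 0) d / se else ifelse(d == 0, 0, Inf * sign(d))
  list(slope_diff = d, se = se, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Significance test of an annual percent change
#'
#' Two-sided test of the null hypothesis of no trend (slope = 0) against the
#' standard normal reference.
#'
#' @param fit An [apc_fit()] object.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `z`, `p_value`, `significant`.
#' @export
test_apc <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "apc_fit"))
  list(z = fit$z, p_value = fit$p_value, significant = fit$p_value < alpha)
}

#' @export
print.apc_fit <- function(x, digits = 3, ...) {
  lab <- if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  cat(sprintf("Weighted log-linear trend fit%s\n", lab))
  cat(sprintf("  APC: %.*f %%/yr (95%% CI %.*f, %.*f), p = %s\n",
              1, x$apc, 1, x$apc_ci[1], 1, x$apc_ci[2],
              format.pval(x$p_value, digits = digits)))
  cat(sprintf("  modeled %d rate: %.1f per 100 000 (SE %.2f)\n",
              x$anchor, x$anchor_rate, x$anchor_rate_se))
  invisible(x)
}

#' @export
summary.apc_fit <- function(object, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- b / se
  tab <- cbind(Estimate = b, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, apc = object$apc, apc_se = object$apc_se,
              apc_ci = object$apc_ci, p_value = object$p_value,
              anchor = object$anchor, anchor_rate = object$anchor_rate,
              anchor_rate_se = object$anchor_rate_se, n = object$n,
              label = object$label)
  class(out) <- "summary.apc_fit"
  out
}

#' @export
print.summary.apc_fit <- function(x, ...) {
  lab <- if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  cat(sprintf("Weighted log-linear trend fit%s (n = %s years)\n", lab, x$n))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nAPC: %.2f %%/yr (SE %.2f; 95%% CI %.2f, %.2f), p = %s\n",
              x$apc, x$apc_se, x$apc_ci[1], x$apc_ci[2],
              format.pval(x$p_value)))
  cat(sprintf("Modeled %d rate: %.1f per 100 000 (SE %.2f)\n",
              x$anchor, x$anchor_rate, x$anchor_rate_se))
  invisible(x)
}

#' @export
plot.apc_fit <- function(x, project_to = NULL, ...) {
  if (is.null(x$model)) stop("no data component in this fit", call. = FALSE)
  d <- x$model
  years <- d$year
  if (!is.null(project_to)) years <- min(years):project_to
  pred <- predict(x, years)
  ylim <- range(c(d$rate - 1.96 * d$se, d$rate + 1.96 * d$se, pred))
  graphics::plot(d$year, d$rate, pch = 19, xlim = range(years), ylim = ylim,
                 xlab = "year", ylab = "rate per 100 000",
                 main = if (!is.null(x$label)) x$label else "event rate trend",
                 ...)
  graphics::arrows(d$year, d$rate - 1.96 * d$se, d$year, d$rate + 1.96 * d$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(years, pred, lty = 1)
  if (!is.null(project_to)) {
    graphics::abline(v = x$anchor, lty = 3)
    stable <- predict(x, years[years > x$anchor], strategy = "stable")
    graphics::lines(as.numeric(names(stable)), stable, lty = 2)
  }
  invisible(x)
}

#' Fit trend models for every sex/age stratum
#'
#' Splits a stratified rate table by sex and age group and fits
#' [apc_fit()] to each stratum over the requested window.
#'
#' @param rates Data frame from [compute_rates()] (columns `year`, `sex`,
#'   `age_group`, `rate`, `se`).
#' @param window Years to fit over (e.g. `2006:2011`).
#' @param anchor Anchor year; defaults to the last window year.
#' @return A named list of `apc_fit` objects (class `apc_fit_list`), keyed by
#'   `"sex:age_group"`. `as.data.frame()` renders the usual summary table.
#' @export
fit_trends <- function(rates, window = NULL, anchor = NULL) {
  st <- mh_strata()
  fits <- lapply(seq_len(nrow(st)), function(i) {
    d <- rates[rates$sex == st$sex[i] & rates$age_group == st$age_group[i], ]
    if (!nrow(d)) {
      stop(sprintf("no rates for stratum %s %s", st$sex[i], st$age_group[i]),
           call. = FALSE)
    }
    apc_fit(rate ~ year, d, se = "se", window = window, anchor = anchor,
            label = sprintf("%s %s", st$sex[i], st$age_group[i]))
  })
  names(fits) <- stratum_key(st$sex, st$age_group)
  class(fits) <- "apc_fit_list"
  fits
}

#' @export
as.data.frame.apc_fit_list <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x), function(key) {
    f <- x[[key]]
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    data.frame(sex = parts[1], age_group = parts[2],
               slope = f$coefficients[["slope"]], slope_se = f$slope_se,
               apc = f$apc, apc_lo = f$apc_ci[1], apc_hi = f$apc_ci[2],
               p_value = f$p_value, anchor = f$anchor,
               anchor_rate = f$anchor_rate,
               anchor_rate_se = f$anchor_rate_se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.apc_fit_list <- function(x, ...) {
  tab <- as.data.frame(x)
  cat(sprintf("Trend fits for %d strata (anchor year %d)\n",
              length(x), tab$anchor[1]))
  show <- data.frame(
    sex = tab$sex, age_group = tab$age_group,
    apc = sprintf("%+.1f (%.1f, %.1f)", tab$apc, tab$apc_lo, tab$apc_hi),
    p = format.pval(tab$p_value, digits = 2),
    modeled_rate = sprintf("%.1f", tab$anchor_rate)
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
`[.apc_fit_list` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "apc_fit_list"
  out
}
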
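#' Events prevented relative to a counterfactual baseline
#'
#' Compares observed event totals against the expected totals from a baseline
#' strategy. The sign convention is fixed throughout the package:
#' `prevented = expected - observed`, so positive values are events
#' prevented and negative values are excess events. The variance of the
#' difference sums the observed and expected variances (the observed total is
#' itself a survey estimate; set `observed_fixed = TRUE` to treat it as
#' known), giving `z = prevented / sqrt(var)` and a symmetric normal 95% CI.
#' Differences with `|z| >= 1.96` are flagged statistically significant.
#'
#' @param observed,expected Event totals (numeric, same scope and period).
#' @param observed_sd,expected_sd Their standard deviations.
#' @param strategy Baseline strategy label carried through (`"stable"` or
#'   `"trend"`).
#' @param scope Free-text scope label (e.g. `"overall"`, `"men 45-64"`).
#' @param years Years covered (collapsed into a label).
#' @param observed_fixed If `TRUE`, the observed total is treated as exact
#'   (its variance is dropped from the z denominator).
#' @return A one-row data frame of class `mh_prevented` with columns
#'   `strategy`, `scope`, `years`, `observed`, `observed_sd`, `expected`,
#'   `expected_sd`, `prevented`, `ci_lo`, `ci_hi`, `z`, `significant`.
#' @examples
#' events_prevented(observed = 100, observed_sd = 0,
#'                  expected = 110, expected_sd = 5)  # prevented 10, z 2
#' @export
events_prevented <- function(observed, expected, observed_sd = 0,
                             expected_sd = 0,
                             strategy = c("stable", "trend"),
                             scope = "overall", years = NA,
                             observed_fixed = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(observed >= 0, expected >= 0, observed_sd >= 0, expected_sd >= 0)
  if (observed_fixed) observed_sd <- 0
  prevented <- expected - observed
  v <- observed_sd^2 + expected_sd^2
  if (v == 0 && prevented != 0) {
    warning("zero combined variance with a nonzero difference; z is infinite",
            call. = FALSE)
    z <- Inf * sign(prevented)
  } else if (v == 0) {
    z <- 0
  } else {
    z <- prevented / sqrt(v)
  }
  out <- data.frame(
    strategy = strategy, scope = scope,
    years = paste(years, collapse = ","),
    observed = observed, observed_sd = observed_sd,
    expected = expected, expected_sd = expected_sd,
    prevented = prevented,
    ci_lo = prevented - 1.96 * sqrt(v),
    ci_hi = prevented + 1.96 * sqrt(v),
    z = z, significant = abs(z) >= 1.96,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mh_prevented", "data.frame")
  out
}

#' Combine prevented-events results across disjoint scopes
#'
#' Sums the observed-vs-expected differences of several results and their
#' variances (independence across the combined units), then recomputes the z
#' score and CI from the combined difference and variance. All results must
#' share one baseline strategy. Intended for disjoint scopes (e.g. summing
#' strata); for multiple years derived from the same fitted baseline, prefer
#' draw-level aggregation (see [run_pipeline()]), which accounts for the
#' shared-fit covariance that the independence assumption here ignores.
#'
#' @param results A data frame of class `mh_prevented` (rows to combine) or a
#'   list of such data frames.
#' @param scope Label for the combined scope.
#' @return A one-row `mh_prevented` data frame.
#' @examples
#' a <- events_prevented(100, 110, 0, 5, scope = "men")
#' b <- events_prevented(100, 110, 0, 5, scope = "women")
#' combine_prevented(rbind(a, b))$z  # 20 / sqrt(50) = 2.83
#' @export
combine_prevented <- function(results, scope = "combined") {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  if (length(unique(results$strategy)) != 1L) {
    stop("cannot combine results across different baseline strategies",
         call. = FALSE)
  }
  v <- sum(results$observed_sd^2 + results$expected_sd^2)
  prevented <- sum(results$prevented)
  z <- if (v > 0) prevented / sqrt(v) else if (prevented == 0) 0 else
    Inf * sign(prevented)
  out <- data.frame(
    strategy = results$strategy[1], scope = scope,
    years = paste(sort(unique(unlist(strsplit(results$years, ",")))),
                  collapse = ","),
    observed = sum(results$observed),
    observed_sd = sqrt(sum(results$observed_sd^2)),
    expected = sum(results$expected),
    expected_sd = sqrt(sum(results$expected_sd^2)),
    prevented = prevented,
    ci_lo = prevented - 1.96 * sqrt(v),
    ci_hi = prevented + 1.96 * sqrt(v),
    z = z, significant = abs(z) >= 1.96,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mh_prevented", "data.frame")
  out
}

#' @export
print.mh_prevented <- function(x, ...) {
  cat("Events prevented (positive) / excess events (negative)\n")
  show <- data.frame(
    strategy = x$strategy, scope = x$scope, years = x$years,
    observed = round(x$observed), expected = round(x$expected),
    prevented = sprintf("%d (%d, %d)", round(x$prevented), round(x$ci_lo),
                        round(x$ci_hi)),
    z = sprintf("%.2f%s", x$z, ifelse(x$significant, " *", ""))
  )
  print(show, row.names = FALSE)
  invisible(x)
}
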
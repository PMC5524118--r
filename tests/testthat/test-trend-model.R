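test_that("a flat series gives APC 0 and p = 1", {
  d <- data.frame(year = 2006:2011, rate = 500, se = 5)
  fit <- apc_fit(rate ~ year, d)
  expect_equal(fit$apc, 0, tolerance = 1e-12)
  expect_equal(fit$p_value, 1, tolerance = 1e-12)
  expect_equal(fit$anchor_rate, 500, tolerance = 1e-9)
})

test_that("an exact exponential series is recovered exactly", {
  d <- data.frame(year = 2006:2011, rate = 100 * 0.98^(0:5))
  fit <- apc_fit(rate ~ year, d, se = rep(1, 6), anchor = 2011)
  expect_equal(fit$apc, -2, tolerance = 1e-10)
  expect_equal(fit$anchor_rate, 100 * 0.98^5, tolerance = 1e-10)
  expect_equal(coef(fit)[["slope"]], log(0.98), tolerance = 1e-12)
  # near-noiseless series: the trend is overwhelmingly significant
  fit2 <- apc_fit(rate ~ year, d, se = 1e-4 * d$rate)
  expect_lt(fit2$p_value, 1e-3)
})

test_that("the WLS solution matches brute-force normal equations to 1e-10", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(4:10, 1)
    d <- data.frame(year = 2000 + seq_len(n),
                    rate = exp(rnorm(n, 5, 0.3)))
    d$se <- d$rate * runif(n, 0.01, 0.1)
    anchor <- max(d$year)
    fit <- apc_fit(rate ~ year, d, anchor = anchor)
    bf <- brute_force_wls(d$year, log(d$rate), (d$rate / d$se)^2, anchor)
    expect_equal(coef(fit)[["slope"]], bf$slope, tolerance = 1e-10)
    expect_equal(coef(fit)[["log_rate_anchor"]], bf$intercept,
                 tolerance = 1e-10)
    expect_equal(unname(vcov(fit)), unname(bf$vcov), tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(year = 2006:2011, rate = 100, se = 1)
  expect_error(apc_fit(rate ~ year, d[1:2, ]), "at least 3")
  d2 <- d; d2$rate[3] <- 0
  expect_error(apc_fit(rate ~ year, d2), "positive")
  d3 <- d; d3$se[2] <- 0
  expect_error(apc_fit(rate ~ year, d3), "SEs must be positive")
})

test_that("scaling all rates leaves slope, APC and p unchanged and scales the anchor rate", {
  set.seed(8)
  d <- rate_stratum(base = 400, apc = -1.5)
  fit <- apc_fit(rate ~ year, d)
  d2 <- transform(d, rate = 3 * rate, se = 3 * se)
  fit2 <- apc_fit(rate ~ year, d2)
  expect_equal(fit2$apc, fit$apc, tolerance = 1e-10)
  expect_equal(fit2$p_value, fit$p_value, tolerance = 1e-10)
  expect_equal(fit2$anchor_rate, 3 * fit$anchor_rate, tolerance = 1e-8)
})

test_that("the slope test follows the normal reference", {
  d <- data.frame(year = 2006:2011, rate = 500, se = 5)
  fit <- apc_fit(rate ~ year, d)
  expect_equal(test_apc(fit)$p_value, 1)
  expect_false(test_apc(fit)$significant)
  # z of 1.96 corresponds to p of 0.05
  f <- apc_summary_fit(anchor_rate = 100, apc = -2, anchor = 2011,
                       apc_se = 100 * 0.98 * (-log(0.98) / 1.96))
  expect_equal(f$p_value, 2 * pnorm(-1.96), tolerance = 1e-6)
})

test_that("APC comparison across strata behaves as a two-sample z-test", {
  d <- data.frame(year = 2006:2011, rate = 100 * 0.98^(0:5))
  fit <- apc_fit(rate ~ year, d, se = 0.03 * d$rate)
  cmp <- compare_apc(fit, fit)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)

  # slopes 3.92 pooled SEs apart give p about 1e-4
  a <- apc_summary_fit(100, -2, 2011, apc_se = 0.5)
  se_slope <- a$slope_se
  apc_b <- 100 * (exp(a$coefficients[["slope"]] +
                        3.92 * sqrt(2) * se_slope) - 1)
  b <- apc_summary_fit(100, apc_b, 2011,
                       apc_se = 100 * (1 + apc_b / 100) * se_slope)
  cmp <- compare_apc(b, a)
  expect_equal(cmp$z, 3.92, tolerance = 1e-6)
  expect_equal(cmp$p_value, 2 * pnorm(-3.92), tolerance = 1e-6)
})

test_that("comparing strata with equal true APCs rejects at the nominal 5% level", {
  set.seed(314)
  nrep <- 1000
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    a <- apc_fit(rate ~ year, rate_stratum(base = 300, apc = -2))
    b <- apc_fit(rate ~ year, rate_stratum(base = 800, apc = -2))
    rej[r] <- compare_apc(a, b)$p_value < 0.05
  }
  tol <- 3 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(mean(rej) - 0.05), tol)
})

test_that("the generator's APC is recovered without bias through the full count pipeline", {
  nrep <- 200
  apcs <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- calib_config(seed = 3000 + r, true_apc = -2.1)
    ds <- simulate_events(cfg)
    totals <- combine_sources(tabulate_counts(apply_exclusions(
      classify_events(ds$records))))
    rates <- compute_rates(totals, ds$population)
    d <- rates[rates$sex == "women" & rates$age_group == "45-64" &
                 rates$year <= 2011, ]
    apcs[r] <- apc_fit(rate ~ year, d)$apc
  }
  mc_se <- stats::sd(apcs) / sqrt(nrep)
  expect_lt(abs(mean(apcs) - (-2.1)), 3 * mc_se)
})

test_that("fit_trends fits every stratum and renders a summary table", {
  cfg <- small_config(seed = 5)
  ds <- simulate_events(cfg)
  rates <- compute_rates(
    combine_sources(tabulate_counts(apply_exclusions(
      classify_events(ds$records)))),
    ds$population)
  fits <- fit_trends(rates, window = 2006:2011)
  expect_length(fits, 8)
  tab <- as.data.frame(fits)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$apc_lo <= tab$apc & tab$apc <= tab$apc_hi))
  expect_true(all(tab$anchor == 2011))
  expect_true(all(sign(tab$apc) == sign(tab$slope)))
})
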
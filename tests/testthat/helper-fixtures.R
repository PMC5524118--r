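# Shared fixtures: toy case definitions and scaled-down generator configs.

toy_defs <- function() {
  as_case_definitions(list(
    ami = list(mi = list(ed_hosp_codes = list("410"),
                         death_codes = list("I21", "I22"))),
    stroke = list(ischemic = list(ed_hosp_codes = list("433", "434"),
                                  death_codes = list("I63"))),
    other_cvd = list(hf = list(ed_hosp_codes = list("428"),
                               death_codes = list("I50")))
  ))
}

# small all-purpose config for module tests
small_config <- function(years = 2006:2011, ...) {
  sim_config(years = years, population = 20000, ...)
}

# calibration-scale config: populations and ED weights chosen so that every
# dominant source count is large enough for the normal approximations the
# inference relies on (per-cell counts in the hundreds to thousands)
calib_config <- function(seed, true_apc = 0, ...) {
  sim_config(true_apc = true_apc, population = 60000,
             ed_weight_model = list(mean = 2, sdlog = 0.3),
             seed = seed, ...)
}

# rate-level synthetic stratum: multiplicative noise with declared relative SE
rate_stratum <- function(years = 2006:2011, base = 100, apc = -2,
                         rel_se = 0.03) {
  truth <- base * (1 + apc / 100)^(years - min(years))
  rate <- truth * (1 + rel_se * stats::rnorm(length(years)))
  while (any(rate <= 0)) {
    bad <- rate <= 0
    rate[bad] <- truth[bad] * (1 + rel_se * stats::rnorm(sum(bad)))
  }
  data.frame(year = years, rate = rate, se = rel_se * rate)
}

# brute-force weighted least squares via explicit normal equations,
# independent of the fitting code
brute_force_wls <- function(year, lograte, w, anchor) {
  x <- cbind(1, year - anchor)
  xtwx <- t(x) %*% (w * x)
  xtwy <- t(x) %*% (w * lograte)
  beta <- solve(xtwx, xtwy)
  list(intercept = beta[1], slope = beta[2], vcov = solve(xtwx))
}
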
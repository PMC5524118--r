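test_that("identical seed and config give byte-identical datasets", {
  cfg <- small_config(years = 2006:2008, seed = 11)
  a <- simulate_events(cfg)
  b <- simulate_events(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$population, b$population)
  c <- simulate_events(cfg, seed = 12)
  expect_false(identical(a$records, c$records))
})

test_that("noiseless generation with no exclusions matches the closed form exactly", {
  cfg <- sim_config(
    years = 2006:2008, base_rate = 1000, true_apc = -2, population = 1e6,
    noise_model = "none", noncase_fraction = 0,
    disposition_probs = list(ed = numeric(0), hospitalization = numeric(0),
                             death = numeric(0)),
    seed = 3
  )
  ds <- simulate_events(cfg)
  retained <- apply_exclusions(classify_events(ds$records))
  counts <- tabulate_counts(retained)
  totals <- combine_sources(counts)
  exp_tot <- stats::aggregate(list(expected = expected_counts(cfg)$expected_count),
                              expected_counts(cfg)[c("year", "sex", "age_group")],
                              sum)
  m <- merge(totals, exp_tot, by = c("year", "sex", "age_group"))
  expect_equal(m$count, m$expected, tolerance = 1e-9)
  # year-1 expectation under a -2% APC: 10000 * 0.98 = 9800 per stratum
  y1 <- m[m$year == 2007, ]
  expect_equal(y1$count, rep(9800, nrow(y1)), tolerance = 1e-9)
})

test_that("flat trends keep counts constant up to Poisson noise", {
  cfg <- small_config(true_apc = 0, seed = 21, noncase_fraction = 0)
  ds <- simulate_events(cfg)
  retained <- apply_exclusions(ds$records)
  totals <- combine_sources(tabulate_counts(retained))
  # men 45-64: expected count identical across years; sd ~ declared
  d <- totals[totals$sex == "men" & totals$age_group == "45-64", ]
  expect_true(max(abs(d$count - mean(d$count))) < 6 * mean(d$sd))
})

test_that("true_parameters returns the generating values verbatim", {
  cfg <- small_config(true_apc = -2.1)
  tp <- true_parameters(cfg)
  expect_equal(unique(tp$true_apc), -2.1)
  # consecutive-year ratio is 1 + APC/100 = 0.979 by definition
  d <- tp[tp$sex == "women" & tp$age_group == "65-74", ]
  d <- d[order(d$year), ]
  expect_equal(d$true_rate[-1] / d$true_rate[-nrow(d)],
               rep(0.979, nrow(d) - 1), tolerance = 1e-12)
  # year-5 rate is base * 0.979^5
  expect_equal(d$true_rate[6], d$true_rate[1] * 0.979^5, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(base_rate = -5), "positive")
  expect_error(sim_config(population = 0), "positive")
  expect_error(sim_config(source_mix = c(ed = 0.5, hospitalization = 0.4,
                                         death = 0.4)), "sum to 1")
  expect_error(
    sim_config(disposition_probs = list(ed = c(died_in_facility = 1.2),
                                        hospitalization = numeric(0),
                                        death = numeric(0))),
    "\\[0, 1\\]")
})

test_that("Monte Carlo mean of post-exclusion counts matches the closed form", {
  nrep <- 200
  cells <- expand.grid(sex = "men", age_group = c("45-64", "75+"),
                       source = mh_sources(), stringsAsFactors = FALSE)
  sums <- matrix(0, nrep, nrow(cells))
  for (r in seq_len(nrep)) {
    cfg <- sim_config(years = 2006:2006, population = 20000,
                      noncase_fraction = 0, seed = 500 + r)
    ds <- simulate_events(cfg)
    counts <- tabulate_counts(apply_exclusions(ds$records))
    for (k in seq_len(nrow(cells))) {
      sel <- counts$sex == cells$sex[k] &
        counts$age_group == cells$age_group[k] &
        counts$source == cells$source[k]
      sums[r, k] <- sum(counts$count[sel])
    }
  }
  cfg <- sim_config(years = 2006:2006, population = 20000,
                    noncase_fraction = 0, seed = 1)
  ec <- expected_counts(cfg)
  for (k in seq_len(nrow(cells))) {
    expected <- ec$expected_count[ec$sex == cells$sex[k] &
                                    ec$age_group == cells$age_group[k] &
                                    ec$source == cells$source[k]]
    mc_se <- stats::sd(sums[, k]) / sqrt(nrep)
    expect_lt(abs(mean(sums[, k]) - expected), 3 * mc_se + 1e-9)
  }
})

test_that("disposition-flag frequencies match their probabilities", {
  cfg <- sim_config(years = 2006:2007, population = 300000, seed = 99,
                    noncase_fraction = 0)
  ds <- simulate_events(cfg)
  for (src in c("ed", "hospitalization")) {
    recs <- ds$records[ds$records$source == src, ]
    probs <- cfg$disposition_probs[[src]]
    for (f in names(probs)) {
      hit <- grepl(f, recs$flags, fixed = TRUE)
      p_hat <- mean(hit)
      tol <- 3 * sqrt(probs[[f]] * (1 - probs[[f]]) / nrow(recs))
      expect_lt(abs(p_hat - probs[[f]]), tol + 1e-9)
    }
  }
  # death records never carry flags
  expect_true(all(ds$records$flags[ds$records$source == "death"] == ""))
})
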
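test_that("classification prefix-matches dot-stripped codes within the right code system", {
  defs <- toy_defs()
  recs <- data.frame(
    source = c("hospitalization", "ed", "death", "death", "hospitalization"),
    code = c("410.71", "433.10", "I21", "410", "V58.1"),
    stringsAsFactors = FALSE
  )
  out <- classify_events(recs, defs, drop_noncase = FALSE)
  expect_equal(out$category,
               c("ami", "stroke", "ami", NA, NA))
  # death codes never match the ED/hospitalization lists and vice versa:
  # "410" as a death record is a non-case
  expect_true(is.na(out$category[4]))
  # non-case codes are dropped by default
  expect_equal(nrow(classify_events(recs, defs)), 3)
})

test_that("a code list placing one pattern in two categories is rejected", {
  expect_error(
    as_case_definitions(list(
      ami = list(a = list(ed_hosp_codes = list("410"), death_codes = list())),
      stroke = list(b = list(ed_hosp_codes = list("410"), death_codes = list()))
    )),
    "more than one"
  )
  # overlap by prefix across categories is caught at classification time
  defs <- as_case_definitions(list(
    ami = list(a = list(ed_hosp_codes = list("410"), death_codes = list())),
    stroke = list(b = list(ed_hosp_codes = list("4107"), death_codes = list()))
  ))
  recs <- data.frame(source = "ed", code = "410.71", stringsAsFactors = FALSE)
  expect_error(classify_events(recs, defs), "more than one")
})

test_that("the exclusion cascade retains exactly the unflagged eligible records", {
  recs <- data.frame(
    source = c(rep("ed", 5), rep("hospitalization", 5)),
    flags = c("admitted_same_hospital", "admitted_same_hospital",
              "died_in_facility", "", "",
              "elective", "transferred_out", "", "", ""),
    stringsAsFactors = FALSE
  )
  kept <- apply_exclusions(recs)
  expect_equal(sum(kept$source == "ed"), 2)
  expect_equal(sum(kept$source == "hospitalization"), 3)

  # no flags -> no-op
  clean <- data.frame(source = rep("ed", 10), flags = "",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(apply_exclusions(clean)), 10)

  # death records are exempt even with a stray (known) flag
  death <- data.frame(source = "death", flags = "died_in_facility",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(apply_exclusions(death)), 1)

  # unknown flag tokens are an input error
  bad <- data.frame(source = "ed", flags = "left_against_advice",
                    stringsAsFactors = FALSE)
  expect_error(apply_exclusions(bad), "unknown disposition flag")
})

test_that("tabulation sums weights and applies the configured SD model", {
  recs <- data.frame(
    source = "ed", year = 2013, sex = "men", age_group = "45-64",
    code = "410", flags = "", weight = c(10, 10, 5),
    stringsAsFactors = FALSE
  )
  cell <- function(counts) {
    counts[counts$source == "ed" & counts$sex == "men" &
             counts$age_group == "45-64", ]
  }
  counts <- tabulate_counts(recs, model = sd_model(type = "relative"))
  expect_equal(cell(counts)$count, 25)

  # single unit-weight record
  one <- recs[1, ]; one$weight <- 1
  expect_equal(cell(tabulate_counts(one))$count, 1)

  # 1000 unit-weight records under the pure relative model: sd = 30
  many <- recs[rep(1, 1000), ]; many$weight <- 1
  counts <- tabulate_counts(many, model = sd_model(ed = 0.03, type = "relative"))
  expect_equal(cell(counts)$sd, 30)

  # design model for unit weights reduces to Poisson + relative terms
  counts <- tabulate_counts(many, model = sd_model(ed = 0.03, type = "design"))
  expect_equal(cell(counts)$sd, sqrt(1000 + 30^2))

  expect_error(tabulate_counts(transform(recs, weight = -1)),
               "non-negative")
})

test_that("tabulation equals brute-force per-record accumulation on small fixtures", {
  set.seed(42)
  n <- 50
  recs <- data.frame(
    source = sample(mh_sources(), n, replace = TRUE),
    year = sample(2006:2008, n, replace = TRUE),
    sex = sample(mh_sexes(), n, replace = TRUE),
    age_group = sample(mh_age_groups(), n, replace = TRUE),
    code = "410", flags = "",
    weight = round(runif(n, 1, 30), 2),
    stringsAsFactors = FALSE
  )
  counts <- tabulate_counts(recs)
  for (k in sample(nrow(counts), 20)) {
    manual <- 0
    for (i in seq_len(n)) {
      if (recs$source[i] == counts$source[k] &&
          recs$year[i] == counts$year[k] &&
          recs$sex[i] == counts$sex[k] &&
          recs$age_group[i] == counts$age_group[k]) {
        manual <- manual + recs$weight[i]
      }
    }
    expect_equal(counts$count[k], manual)
  }
})

test_that("combining sources sums counts and pools variances", {
  x <- data.frame(
    year = 2013, sex = "men", age_group = "45-64",
    source = mh_sources(), count = c(343214, 2099874, 386073),
    sd = c(3, 0, 4), stringsAsFactors = FALSE
  )
  out <- combine_sources(x)
  expect_equal(out$count, 2829161)
  expect_equal(out$sd, 5)

  zero <- transform(x, count = 0, sd = 0)
  out <- combine_sources(zero)
  expect_equal(out$count, 0)
  expect_equal(out$sd, 0)

  dup <- rbind(x, x[1, ])
  expect_error(combine_sources(dup), "duplicate")
})

test_that("category totals partition the all-category total and exclusions never increase counts", {
  cfg <- small_config(years = 2006:2007, seed = 7)
  ds <- simulate_events(cfg)
  cases <- classify_events(ds$records)
  retained <- apply_exclusions(cases)

  by_cat <- combine_sources(tabulate_counts(retained, by_category = TRUE),
                            by_category = TRUE)
  total <- combine_sources(tabulate_counts(retained))
  rolled <- stats::aggregate(list(count = by_cat$count),
                             by_cat[c("year", "sex", "age_group")], sum)
  m <- merge(total, rolled, by = c("year", "sex", "age_group"))
  expect_equal(m$count.x, m$count.y, tolerance = 1e-9)

  pre <- tabulate_counts(cases)
  post <- tabulate_counts(retained)
  m2 <- merge(pre, post, by = c("year", "sex", "age_group", "source"))
  expect_true(all(m2$count.y <= m2$count.x + 1e-9))

  # each retained record lands in exactly one source total
  expect_equal(sum(post$count), sum(retained$weight), tolerance = 1e-9)
})
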
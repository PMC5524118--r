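#' Configuration for the synthetic multi-source event generator
#'
#' Builds the configuration object consumed by [simulate_events()]. The
#' generator emulates the statistical structure of three administrative
#' sources — a survey-weighted emergency-department (ED) sample, a near-census
#' hospitalization file, and a death registry — with stratum-level true event
#' rates that follow log-linear trends (constant annual percent change, APC)
#' plus sampling noise, so that every downstream stage of the pipeline can be
#' exercised against known ground truth.
#'
#' @details
#' Per stratum `s` and year `y`, the true pre-exclusion event rate per
#' 100 000 is
#' `base_rate(s) * (1 + true_apc(s)/100)^(y - min(years))`,
#' optionally multiplied by `shift_ratio` from `shift_year` onward (used to
#' inject post-baseline rate deficits in calibration studies). Events are
#' allocated to sources by `source_mix`; each record independently receives
#' disposition flags per `disposition_probs`, so the expected
#' *post-exclusion* weighted count in source `src` is
#' `population * rate / 1e5 * source_mix[src] * prod(1 - disposition_probs[[src]])`.
#'
#' Under `noise_model = "poisson"`, source-level counts are drawn Poisson
#' around a gamma-distributed rate multiplier with relative dispersion
#' `rel_dispersion[src]` (mean 1), mimicking survey design noise on top of
#' count-level sampling; `"none"` reproduces the expectation exactly
#' (fractional-weight remainder records are used so weighted totals match the
#' closed form). ED records carry lognormal survey weights with mean
#' `ed_weight_model$mean`; hospitalization and death records have weight 1.
#'
#' Default rates and APCs correspond to national adult cardiovascular
#' surveillance conditions (2011 anchor rates from roughly 106 to 7000 per
#' 100 000 across the eight sex/age strata, APCs between -1.1 and -3.4 % per
#' year); default populations are 1/100 of the 2010 US adult census
#' distribution so a default run stays small.
#'
#' @param years Inclusive range of calendar years to simulate.
#' @param true_apc Per-stratum APC in percent per year (length 1 or 8, named
#'   by `"sex:age_group"` or in [mh_strata()] order).
#' @param base_rate Per-stratum pre-exclusion event rate per 100 000 at
#'   `min(years)`. Default back-projects the default 2011 anchor rates to the
#'   start year using `true_apc`.
#' @param population Per-stratum person denominator (constant across years).
#' @param source_mix Named proportions of candidate events landing in each
#'   source; must sum to 1.
#' @param disposition_probs Named list per source of per-flag probabilities.
#' @param ed_weight_model List with `mean` (> 1) and `sdlog` for ED lognormal
#'   survey weights.
#' @param rel_dispersion Per-source relative SE of the survey-like rate
#'   multiplier (0 disables it).
#' @param noise_model `"poisson"` or `"none"`.
#' @param defs Case definitions used to sample diagnosis codes, see
#'   [default_case_definitions()].
#' @param category_mix Named proportions of case events per category.
#' @param noncase_fraction Expected number of non-case records generated per
#'   case record, so classification has true negatives.
#' @param noncase_codes List with `ed_hosp` and `death` character vectors of
#'   non-case codes.
#' @param shift_year,shift_ratio Optional level shift: rates for years
#'   `>= shift_year` are multiplied by `shift_ratio`.
#' @param seed Master integer seed; per-stratum substreams are derived from it
#'   deterministically, so adding strata does not reshuffle existing draws.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_events()], [true_parameters()], [expected_counts()]
#' @export
sim_config <- function(years = 2006:2013,
                       true_apc = c("men:18-44" = -2.1, "men:45-64" = -1.1,
                                    "men:65-74" = -2.7, "men:75+" = -1.7,
                                    "women:18-44" = -1.4, "women:45-64" = -1.7,
                                    "women:65-74" = -3.4, "women:75+" = -1.6),
                       base_rate = NULL,
                       population = c("men:18-44" = 556000, "men:45-64" = 404000,
                                      "men:65-74" = 101000, "men:75+" = 72000,
                                      "women:18-44" = 553000, "women:45-64" = 424000,
                                      "women:65-74" = 116000, "women:75+" = 114000),
                       source_mix = c(ed = 0.147, hospitalization = 0.732,
                                      death = 0.121),
                       disposition_probs = list(
                         ed = c(died_in_facility = 0.01, transferred_out = 0.02,
                                admitted_same_hospital = 0.25),
                         hospitalization = c(elective = 0.05,
                                             died_in_facility = 0.04,
                                             transferred_out = 0.02),
                         death = numeric(0)
                       ),
                       ed_weight_model = list(mean = 20, sdlog = 0.5),
                       rel_dispersion = c(ed = 0.03, hospitalization = 0,
                                          death = 0.005),
                       noise_model = c("poisson", "none"),
                       defs = default_case_definitions(),
                       category_mix = c(ami = 0.214, stroke = 0.212,
                                        symptomatic_precursor = 0.123,
                                        other_cvd = 0.451),
                       noncase_fraction = 0.1,
                       noncase_codes = list(
                         ed_hosp = c("486", "5990", "4659", "78650"),
                         death = c("C349", "J189", "E119", "A419")
                       ),
                       shift_year = NULL,
                       shift_ratio = 1,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  years <- sort(unique(as.integer(years)))

  true_apc <- as_stratum_vector(true_apc, "true_apc")
  population <- as_stratum_vector(population, "population")
  if (is.null(base_rate)) {
    # defaults are anchored at 2011; back-project to the start year
    anchor <- c("men:18-44" = 152.9, "men:45-64" = 1184.1,
                "men:65-74" = 2827.4, "men:75+" = 7031.0,
                "women:18-44" = 106.3, "women:45-64" = 735.1,
                "women:65-74" = 2069.8, "women:75+" = 6842.6)
    anchor <- as_stratum_vector(anchor, "base_rate")
    base_rate <- anchor / (1 + true_apc / 100)^(2011 - min(years))
  }
  base_rate <- as_stratum_vector(base_rate, "base_rate")

  if (any(base_rate <= 0) || any(population <= 0)) {
    stop("base rates and populations must be positive", call. = FALSE)
  }
  if (any(true_apc <= -100)) {
    stop("true_apc must exceed -100", call. = FALSE)
  }
  srcs <- mh_sources()
  if (!setequal(names(source_mix), srcs)) {
    stop("source_mix must be named ed/hospitalization/death", call. = FALSE)
  }
  source_mix <- source_mix[srcs]
  if (abs(sum(source_mix) - 1) > 1e-8 || any(source_mix < 0)) {
    stop("source_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  for (src in srcs) {
    p <- disposition_probs[[src]]
    if (length(p) && (any(p < 0) || any(p > 1))) {
      stop("disposition probabilities must lie in [0, 1]", call. = FALSE)
    }
    allowed <- exclusion_flags()[[src]]
    if (length(setdiff(names(p), allowed))) {
      stop(sprintf("unknown disposition flag for source '%s'", src),
           call. = FALSE)
    }
  }
  if (ed_weight_model$mean <= 0) {
    stop("ED weight mean must be positive", call. = FALSE)
  }
  rel_dispersion <- rel_dispersion[srcs]
  if (any(is.na(rel_dispersion)) || any(rel_dispersion < 0)) {
    stop("rel_dispersion must be a non-negative value per source",
         call. = FALSE)
  }
  if (abs(sum(category_mix) - 1) > 1e-6) {
    category_mix <- category_mix / sum(category_mix)
  }

  cfg <- list(
    years = years, true_apc = true_apc, base_rate = base_rate,
    population = population, source_mix = source_mix,
    disposition_probs = disposition_probs, ed_weight_model = ed_weight_model,
    rel_dispersion = rel_dispersion, noise_model = noise_model, defs = defs,
    category_mix = category_mix, noncase_fraction = noncase_fraction,
    noncase_codes = noncase_codes, shift_year = shift_year,
    shift_ratio = shift_ratio, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic surveillance configuration\n")
  cat(sprintf("  years: %d-%d, seed %d, noise model '%s'\n",
              min(x$years), max(x$years), x$seed, x$noise_model))
  cat(sprintf("  source mix: ED %.1f%%, hospitalization %.1f%%, death %.1f%%\n",
              100 * x$source_mix[["ed"]],
              100 * x$source_mix[["hospitalization"]],
              100 * x$source_mix[["death"]]))
  st <- true_parameters(x)
  st <- st[st$year == min(x$years), ]
  cat("  strata (start-year rate per 100 000, APC %/yr):\n")
  for (i in seq_len(nrow(st))) {
    cat(sprintf("    %-6s %-6s rate %8.1f  APC %+.1f\n", st$sex[i],
                st$age_group[i], st$true_rate[i], st$true_apc[i]))
  }
  invisible(x)
}

# deterministic per-stratum substream seed (kept below 2^31)
stratum_seed <- function(master, idx) {
  as.integer((as.numeric(master) * 1000003 + idx * 7919) %% 2147483587)
}

# true pre-exclusion rate per 100k for one stratum key across config years
true_rate_path <- function(config, key) {
  y0 <- min(config$years)
  r <- config$base_rate[[key]] *
    (1 + config$true_apc[[key]] / 100)^(config$years - y0)
  if (!is.null(config$shift_year)) {
    r <- r * ifelse(config$years >= config$shift_year, config$shift_ratio, 1)
  }
  r
}

# post-exclusion retention per source = prod(1 - flag probabilities)
source_retention <- function(config) {
  vapply(mh_sources(), function(src) {
    p <- config$disposition_probs[[src]]
    if (length(p)) prod(1 - p) else 1
  }, numeric(1))
}

#' Ground-truth parameters of a synthetic configuration
#'
#' Returns the exact generating values per stratum and year, for
#' parameter-recovery tests: the APC, the pre-exclusion true rate, and the
#' expected post-exclusion observable rate (pre-exclusion rate times the
#' source-mix-weighted retention of the exclusion cascade).
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `sex`, `age_group`, `year`, `true_apc`,
#'   `true_rate`, `observable_rate`.
#' @export
true_parameters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- mh_strata()
  keep <- sum(config$source_mix * source_retention(config))
  out <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    key <- stratum_key(st$sex[i], st$age_group[i])
    r <- true_rate_path(config, key)
    data.frame(sex = st$sex[i], age_group = st$age_group[i],
               year = config$years, true_apc = config$true_apc[[key]],
               true_rate = r, observable_rate = r * keep,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Closed-form expected post-exclusion counts
#'
#' The expectation of the post-exclusion weighted event count per year,
#' stratum, and source implied by a configuration:
#' `population * rate(year) / 1e5 * source_mix * retention`, where retention
#' is the product of `1 - p` over the source's disposition-flag
#' probabilities.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `year`, `sex`, `age_group`, `source`,
#'   `expected_count`.
#' @export
expected_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- mh_strata()
  ret <- source_retention(config)
  out <- list()
  for (i in seq_len(nrow(st))) {
    key <- stratum_key(st$sex[i], st$age_group[i])
    rate <- true_rate_path(config, key)
    lam_tot <- config$population[[key]] * rate / 1e5
    for (src in mh_sources()) {
      out[[length(out) + 1L]] <- data.frame(
        year = config$years, sex = st$sex[i], age_group = st$age_group[i],
        source = src,
        expected_count = lam_tot * config$source_mix[[src]] * ret[[src]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic multi-source event dataset
#'
#' Draws encounter-level records for the three sources (ED, hospitalization,
#' death registry) under the trends and noise model of a [sim_config()], plus
#' the matching population-denominator table. Identical configurations and
#' seeds yield identical output.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional override of `config$seed`.
#' @return A list of class `mh_dataset` with elements `records` (data frame:
#'   `source`, `year`, `sex`, `age_group`, `code`, `flags`, `weight`;
#'   `flags` is a semicolon-joined token string) and `population` (data
#'   frame: `year`, `sex`, `age_group`, `population`).
#' @examples
#' cfg <- sim_config(years = 2006:2008, population = 20000, seed = 7)
#' ds <- simulate_events(cfg)
#' head(ds$records)
#' @export
simulate_events <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  st <- mh_strata()
  noisy <- config$noise_model == "poisson"
  wm <- config$ed_weight_model
  # lognormal with mean wm$mean: meanlog = log(mean) - sdlog^2/2
  meanlog <- log(wm$mean) - wm$sdlog^2 / 2

  defs <- config$defs
  pools <- list(
    ed_hosp = split(defs$pattern[defs$system == "ed_hosp"],
                    defs$category[defs$system == "ed_hosp"]),
    death = split(defs$pattern[defs$system == "death"],
                  defs$category[defs$system == "death"])
  )
  cats <- names(config$category_mix)

  sample_codes <- function(n, system) {
    if (n == 0L) return(character(0))
    cat_draw <- sample(cats, n, replace = TRUE, prob = config$category_mix)
    codes <- character(n)
    for (cc in unique(cat_draw)) {
      idx <- which(cat_draw == cc)
      pool <- pools[[system]][[cc]]
      if (is.null(pool) || !length(pool)) {
        pool <- unlist(pools[[system]], use.names = FALSE)
      }
      codes[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
    # exercise prefix matching: sometimes extend with a subcode digit
    ext <- stats::runif(n) < 0.5
    if (any(ext)) {
      codes[ext] <- paste0(codes[ext], sample(0:9, sum(ext), replace = TRUE))
    }
    if (system == "ed_hosp") {
      long <- nchar(codes) > 3L
      codes[long] <- paste0(substr(codes[long], 1, 3), ".",
                            substring(codes[long], 4))
    }
    codes
  }

  draw_flags <- function(n, src) {
    probs <- config$disposition_probs[[src]]
    if (!length(probs) || n == 0L) return(rep("", n))
    out <- rep("", n)
    for (f in names(probs)) {
      hit <- stats::runif(n) < probs[[f]]
      out[hit] <- ifelse(out[hit] == "", f, paste(out[hit], f, sep = ";"))
    }
    out
  }

  draw_source_records <- function(lam, src) {
    rel <- config$rel_dispersion[[src]]
    if (noisy && rel > 0) {
      shape <- 1 / rel^2
      lam <- lam * stats::rgamma(1L, shape = shape, rate = shape)
    }
    if (src == "ed") {
      if (noisy) {
        n <- stats::rpois(1L, lam / wm$mean)
        w <- stats::rlnorm(n, meanlog = meanlog, sdlog = wm$sdlog)
      } else {
        n <- if (lam > 0) as.integer(ceiling(lam / wm$mean)) else 0L
        w <- rep(lam / max(n, 1L), n)
      }
    } else {
      if (noisy) {
        n <- stats::rpois(1L, lam)
        w <- rep(1, n)
      } else {
        n <- as.integer(floor(lam + 1e-9))
        w <- rep(1, n)
        frac <- lam - n
        if (frac > 1e-9) {
          n <- n + 1L
          w <- c(w, frac)
        }
      }
    }
    list(n = n, w = w)
  }

  acc <- list(source = list(), year = list(), sex = list(), age_group = list(),
              code = list(), flags = list(), weight = list())
  push <- function(src, year, sex, age_group, code, flags, weight) {
    k <- length(acc$source) + 1L
    n <- length(code)
    acc$source[[k]] <<- rep.int(src, n)
    acc$year[[k]] <<- rep.int(year, n)
    acc$sex[[k]] <<- rep.int(sex, n)
    acc$age_group[[k]] <<- rep.int(age_group, n)
    acc$code[[k]] <<- code
    acc$flags[[k]] <<- flags
    acc$weight[[k]] <<- weight
  }
  for (i in seq_len(nrow(st))) {
    set.seed(stratum_seed(seed, i))
    key <- stratum_key(st$sex[i], st$age_group[i])
    rates <- true_rate_path(config, key)
    pop <- config$population[[key]]
    for (yi in seq_along(config$years)) {
      lam_total <- pop * rates[yi] / 1e5
      for (src in mh_sources()) {
        drawn <- draw_source_records(lam_total * config$source_mix[[src]], src)
        n <- drawn$n
        system <- if (src == "death") "death" else "ed_hosp"
        # extra non-case records so classification has true negatives
        n_nc <- if (config$noncase_fraction > 0 && n > 0) {
          if (noisy) stats::rpois(1L, n * config$noncase_fraction)
          else as.integer(round(n * config$noncase_fraction))
        } else 0L
        n_all <- n + n_nc
        if (n_all == 0L) next
        codes <- c(
          sample_codes(n, system),
          if (n_nc > 0L) sample(config$noncase_codes[[system]], n_nc,
                                replace = TRUE) else character(0)
        )
        w_nc <- if (n_nc > 0L) {
          if (src == "ed") {
            if (noisy) stats::rlnorm(n_nc, meanlog = meanlog, sdlog = wm$sdlog)
            else rep(wm$mean, n_nc)
          } else rep(1, n_nc)
        } else numeric(0)
        push(src, config$years[yi], st$sex[i], st$age_group[i], codes,
             draw_flags(n_all, src), c(drawn$w, w_nc))
      }
    }
  }
  records <- data.frame(
    source = unlist(acc$source, use.names = FALSE),
    year = unlist(acc$year, use.names = FALSE),
    sex = unlist(acc$sex, use.names = FALSE),
    age_group = unlist(acc$age_group, use.names = FALSE),
    code = unlist(acc$code, use.names = FALSE),
    flags = unlist(acc$flags, use.names = FALSE),
    weight = unlist(acc$weight, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (!nrow(records)) {
    records <- data.frame(source = character(0), year = integer(0),
                          sex = character(0), age_group = character(0),
                          code = character(0), flags = character(0),
                          weight = numeric(0))
  }

  population <- do.call(rbind, lapply(config$years, function(y) {
    data.frame(year = y, sex = st$sex, age_group = st$age_group,
               population = as.numeric(config$population),
               stringsAsFactors = FALSE)
  }))
  rownames(population) <- NULL

  structure(list(records = records, population = population, config = config),
            class = "mh_dataset")
}

#' @export
print.mh_dataset <- function(x, ...) {
  cat(sprintf("Synthetic event dataset: %d records, years %d-%d\n",
              nrow(x$records), min(x$config$years), max(x$config$years)))
  tab <- table(x$records$source)
  cat("  records by source:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}
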
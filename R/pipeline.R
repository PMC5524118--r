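#' Run the full surveillance and baseline-modeling pipeline
#'
#' Executes every stage in order on a synthetic (or previously loaded)
#' dataset: classify events against the case definition, apply the
#' per-source exclusion cascade, tabulate weighted counts with SDs, combine
#' sources into mutually exclusive totals, compute stratum rates and direct
#' age-standardized rates, fit inverse-variance-weighted log-linear trends
#' over the fit window, project stable and trend counterfactual baselines
#' into the projection window with Monte Carlo uncertainty, and compare
#' observed with expected events to estimate events prevented.
#'
#' Multi-year prevented totals within a stratum are aggregated at the level
#' of the Monte Carlo draws (events summed across years within each draw,
#' then the SD taken across draws), which preserves the covariance induced by
#' the shared fitted baseline; strata are combined assuming independence,
#' which holds because each stratum has its own fit and data.
#'
#' @param config A [sim_config()]; defines the synthetic world.
#' @param dataset Optionally, an existing `mh_dataset` (as returned by
#'   [simulate_events()]); by default one is generated from `config`.
#' @param defs Case definitions (default: the configuration's).
#' @param model Count SD model, see [sd_model()].
#' @param std Standard-population weights, see [standard_population()].
#' @param fit_window Years of the trend fit (default 2006:2011).
#' @param anchor Anchor year (default: last fit-window year).
#' @param project_years Projection window (default 2012:2013); must follow
#'   the anchor and be covered by the dataset for observed comparisons.
#' @param n_sims Monte Carlo replicates per baseline (default 1000).
#' @param seed Seed controlling both data generation (if `dataset` is NULL)
#'   and the baseline simulations.
#' @param observed_fixed Treat observed totals as exact in the z-tests.
#' @return A list of class `mh_run` with elements `counts`, `totals`,
#'   `rates`, `std_rates`, `fits`, `projections`, `prevented` (per
#'   stratum/year), `prevented_by_stratum` (years combined),
#'   `prevented_overall` (strata combined, per year and overall), plus the
#'   inputs used.
#' @examples
#' \donttest{
#' cfg <- sim_config(population = 50000, seed = 42)
#' run <- run_pipeline(cfg, n_sims = 200)
#' run$prevented_overall
#' }
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         defs = config$defs, model = sd_model(),
                         std = standard_population(),
                         fit_window = 2006:2011, anchor = max(fit_window),
                         project_years = 2012:2013, n_sims = 1000,
                         seed = config$seed, observed_fixed = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (max(fit_window) >= min(project_years)) {
    stop("the fit window must precede the projection window", call. = FALSE)
  }
  if (anchor != max(fit_window)) {
    stop("the anchor year must be the last fit-window year", call. = FALSE)
  }

  if (is.null(dataset)) dataset <- simulate_events(config, seed = seed)

  cases <- classify_events(dataset$records, defs)
  retained <- apply_exclusions(cases)
  counts <- tabulate_counts(retained, model = model, by_category = TRUE)
  totals <- combine_sources(counts)
  rates <- compute_rates(totals, dataset$population)
  std_rates <- age_standardize(rates, std)
  fits <- fit_trends(rates, window = fit_window, anchor = anchor)

  st <- mh_strata()
  projections <- list()
  prevented <- list()
  by_stratum <- list()

  for (strategy in c("stable", "trend")) {
    for (i in seq_len(nrow(st))) {
      key <- stratum_key(st$sex[i], st$age_group[i])
      pop_i <- dataset$population[
        dataset$population$sex == st$sex[i] &
          dataset$population$age_group == st$age_group[i], ]
      sim <- simulate_baseline(
        fits[[key]], strategy = strategy, years = project_years,
        n_sims = n_sims,
        seed = stratum_seed(seed + 10007 * (strategy == "trend"), 100 + i),
        keep_draws = TRUE
      )
      exp_ev <- expected_events(sim, pop_i)
      exp_ev$sex <- st$sex[i]
      exp_ev$age_group <- st$age_group[i]
      projections[[length(projections) + 1L]] <- exp_ev

      obs_i <- totals[totals$sex == st$sex[i] &
                        totals$age_group == st$age_group[i] &
                        totals$year %in% project_years, ]
      if (!all(project_years %in% obs_i$year)) next  # no observed data yet

      rows <- lapply(seq_along(project_years), function(k) {
        y <- project_years[k]
        events_prevented(
          observed = obs_i$count[obs_i$year == y],
          observed_sd = obs_i$sd[obs_i$year == y],
          expected = exp_ev$events_mean[exp_ev$year == y],
          expected_sd = exp_ev$events_sd[exp_ev$year == y],
          strategy = strategy,
          scope = sprintf("%s %s", st$sex[i], st$age_group[i]),
          years = y, observed_fixed = observed_fixed
        )
      })
      prevented[[length(prevented) + 1L]] <- do.call(rbind, rows)

      # combined years: aggregate inside the draws to keep the covariance
      ev_draws <- attr(exp_ev, "draws")
      comb_expected <- sum(exp_ev$events_mean)
      comb_expected_sd <- stats::sd(colSums(ev_draws))
      comb <- events_prevented(
        observed = sum(obs_i$count),
        observed_sd = sqrt(sum(obs_i$sd^2)),
        expected = comb_expected, expected_sd = comb_expected_sd,
        strategy = strategy,
        scope = sprintf("%s %s", st$sex[i], st$age_group[i]),
        years = project_years, observed_fixed = observed_fixed
      )
      by_stratum[[length(by_stratum) + 1L]] <- comb
    }
  }

  projections <- do.call(rbind, lapply(projections, function(d) {
    attr(d, "draws") <- NULL
    d[, c("strategy", "sex", "age_group", "year", "rate_mean", "rate_sd",
          "events_mean", "events_sd", "events_lo", "events_hi")]
  }))
  prevented <- if (length(prevented)) do.call(rbind, prevented) else NULL
  by_stratum <- if (length(by_stratum)) do.call(rbind, by_stratum) else NULL

  overall <- NULL
  if (!is.null(prevented)) {
    pieces <- list()
    for (strategy in c("stable", "trend")) {
      for (y in project_years) {
        sel <- prevented[prevented$strategy == strategy &
                           prevented$years == as.character(y), ]
        pieces[[length(pieces) + 1L]] <- combine_prevented(sel, scope = "overall")
      }
      sel <- by_stratum[by_stratum$strategy == strategy, ]
      pieces[[length(pieces) + 1L]] <- combine_prevented(sel, scope = "overall")
    }
    overall <- do.call(rbind, pieces)
  }

  out <- list(
    config = config, dataset = dataset, counts = counts, totals = totals,
    rates = rates, std_rates = std_rates, fits = fits,
    projections = projections, prevented = prevented,
    prevented_by_stratum = by_stratum, prevented_overall = overall,
    fit_window = fit_window, anchor = anchor,
    project_years = project_years, n_sims = n_sims, seed = seed
  )
  class(out) <- "mh_run"
  out
}

#' @export
print.mh_run <- function(x, ...) {
  cat("Cardiovascular event surveillance run\n")
  cat(sprintf("  seed %d; fit window %d-%d (anchor %d); projection %d-%d; %d sims\n",
              x$seed, min(x$fit_window), max(x$fit_window), x$anchor,
              min(x$project_years), max(x$project_years), x$n_sims))
  s <- x$std_rates[x$std_rates$scope == "overall", ]
  first <- s[which.min(s$year), ]
  last_fit <- s[s$year == x$anchor, ]
  if (nrow(last_fit)) {
    cat(sprintf("  overall age-standardized rate: %.1f (%d) -> %.1f (%d), change %.1f%%\n",
                first$rate, first$year, last_fit$rate, last_fit$year,
                relative_change(first$rate, last_fit$rate)))
  }
  cat("\nTrend fits:\n")
  print(x$fits)
  if (!is.null(x$prevented_overall)) {
    cat("\nOverall events prevented (expected - observed):\n")
    print(x$prevented_overall)
  }
  invisible(x)
}

# short digest of the configuration, embedded in output headers
config_hash <- function(config) {
  strip <- config
  strip$defs <- if (!is.null(config$defs)) {
    paste(config$defs$category, config$defs$system, config$defs$pattern,
          collapse = "|")
  }
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(lapply(strip, function(v)
    if (is.numeric(v)) round(unname(v), 10) else v)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write the result tables of a pipeline run to CSV
#'
#' Each file starts with comment lines recording the seed and a digest of the
#' configuration, so outputs are traceable to the run that produced them.
#' Existing files written from a different configuration are not overwritten
#' unless `overwrite = TRUE`.
#'
#' @param run An `mh_run` object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param overwrite Allow replacing existing output files.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(run, dir, overwrite = FALSE) {
  stopifnot(inherits(run, "mh_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- config_hash(run$config)
  header <- c(sprintf("# heartsentinel run; seed: %d; config: %s", run$seed,
                      hash),
              sprintf("# fit window %d-%d; anchor %d; projection %d-%d; n_sims %d",
                      min(run$fit_window), max(run$fit_window), run$anchor,
                      min(run$project_years), max(run$project_years),
                      run$n_sims))
  tables <- list(
    counts = run$counts, totals = run$totals, rates = run$rates,
    standardized_rates = run$std_rates,
    trend_fits = as.data.frame(run$fits), projections = run$projections,
    prevented = run$prevented,
    prevented_by_stratum = run$prevented_by_stratum,
    prevented_overall = run$prevented_overall
  )
  paths <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path) && !overwrite) {
      old <- readLines(path, n = 1L)
      if (!grepl(hash, old, fixed = TRUE)) {
        stop(sprintf("'%s' exists and was written by a different configuration; use overwrite = TRUE",
                     path), call. = FALSE)
      }
    }
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a CSV written by [write_outputs()] (or any CSV with `#` comments)
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_surveillance_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write and read encounter records as CSV
#'
#' Records use the columns `source`, `year`, `sex`, `age_group`, `code`,
#' `flags`, `weight`, with disposition flags semicolon-joined.
#'
#' @param records Data frame of encounter records.
#' @param path File path.
#' @return `read_records_csv()` returns the records data frame.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(
    records[, c("source", "year", "sex", "age_group", "code", "flags",
                "weight")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(code = "character",
                                        flags = "character"))
  out$flags[is.na(out$flags)] <- ""
  out
}
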
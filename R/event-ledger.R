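#' Classify encounter records against the case definition
#'
#' Assigns each record the event category and subtype whose code list it
#' matches, or `NA` for non-cases. ED and hospitalization records are matched
#' against `ed_hosp_codes` patterns only; death records against `death_codes`
#' only (the two code systems never cross). Matching is prefix-based on
#' dot-stripped, upper-cased codes. A code that matches patterns from two
#' different categories indicates a misconfigured definition and raises an
#' error.
#'
#' @param records Data frame of encounter records with at least `source` and
#'   `code` columns (as produced by [simulate_events()]).
#' @param defs Case definitions, see [read_case_definitions()].
#' @param drop_noncase If `TRUE` (default), records matching no definition are
#'   removed; otherwise they are kept with `NA` category.
#' @return `records` with `category` and `subtype` columns added.
#' @export
classify_events <- function(records, defs = default_case_definitions(),
                            drop_noncase = TRUE) {
  stopifnot(is.data.frame(records), all(c("source", "code") %in% names(records)))
  validate_case_definitions(defs)
  norm <- normalize_code(records$code)
  category <- rep(NA_character_, nrow(records))
  subtype <- rep(NA_character_, nrow(records))

  for (sys in c("ed_hosp", "death")) {
    in_sys <- if (sys == "death") records$source == "death"
              else records$source %in% c("ed", "hospitalization")
    if (!any(in_sys)) next
    d <- defs[defs$system == sys, ]
    pat <- normalize_code(d$pattern)
    # codes repeat heavily; classify each distinct code once
    uniq <- unique(norm[in_sys])
    ucat <- rep(NA_character_, length(uniq))
    usub <- rep(NA_character_, length(uniq))
    for (j in seq_along(pat)) {
      hit <- startsWith(uniq, pat[j])
      clash <- hit & !is.na(ucat) & ucat != d$category[j]
      if (any(clash)) {
        stop(sprintf(
          "code '%s' matches more than one event category ('%s' and '%s'); fix the case definitions",
          uniq[which(clash)[1]], ucat[which(clash)[1]], d$category[j]),
          call. = FALSE)
      }
      # keep the first (most specific handling is irrelevant within a category)
      new <- hit & is.na(ucat)
      ucat[new] <- d$category[j]
      usub[new] <- d$subtype[j]
    }
    idx <- match(norm[in_sys], uniq)
    category[in_sys] <- ucat[idx]
    subtype[in_sys] <- usub[idx]
  }
  records$category <- category
  records$subtype <- subtype
  if (drop_noncase) records <- records[!is.na(records$category), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Apply the per-source disposition exclusion cascade
#'
#' Enforces mutual exclusivity of the three sources: ED visit events are
#' dropped when the patient died in the ED, was transferred to another
#' hospital, or was admitted to the same hospital (those episodes surface in
#' the hospitalization or death file); hospitalization events are dropped when
#' elective, or when the patient died in hospital or was transferred out.
#' Death-registry records are never excluded.
#'
#' @param records Data frame with `source` and `flags` columns; `flags` is a
#'   semicolon-joined token string (empty string = no flags).
#' @return The retained records.
#' @export
apply_exclusions <- function(records) {
  stopifnot(is.data.frame(records), all(c("source", "flags") %in% names(records)))
  flags <- ifelse(is.na(records$flags), "", records$flags)
  # flag strings repeat heavily; evaluate each distinct value once
  uniq <- unique(flags)
  tokens <- strsplit(uniq, ";", fixed = TRUE)
  bad <- setdiff(unique(unlist(tokens)), c(all_known_flags(), ""))
  if (length(bad)) {
    stop(sprintf("unknown disposition flag token(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rules <- exclusion_flags()
  idx <- match(flags, uniq)
  drop <- rep(FALSE, nrow(records))
  for (src in names(rules)) {
    if (!length(rules[[src]])) next
    hits <- vapply(tokens, function(tok) any(tok %in% rules[[src]]),
                   logical(1))
    drop <- drop | (records$source == src & hits[idx])
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-source count standard-deviation model
#'
#' Configures how the SD of each weighted source count is synthesized. Two
#' model types are available:
#' \describe{
#'   \item{`"design"`}{`sd = sqrt(sum(w_i^2) + (rel_se * count)^2)` — the
#'     classical variance estimator for a weighted total under Poisson-type
#'     record sampling (`sum(w^2)`, which reduces to the Poisson count
#'     variance for unit weights), plus a relative-SE overdispersion
#'     component. This is the default; it matches the noise model of the
#'     synthetic generator, so downstream inference is calibrated.}
#'   \item{`"relative"`}{`sd = rel_se * count` — a pure relative-SE model
#'     mimicking published survey SDs.}
#' }
#' The default relative SEs are 3\% for the survey-weighted ED source, 0 for
#' the near-census hospitalization source, and 0.5\% for the death registry.
#'
#' @param ed,hospitalization,death Relative SE per source (fractions).
#' @param type `"design"` or `"relative"`.
#' @return A list of class `mh_sd_model`.
#' @export
sd_model <- function(ed = 0.03, hospitalization = 0, death = 0.005,
                     type = c("design", "relative")) {
  type <- match.arg(type)
  rel <- c(ed = ed, hospitalization = hospitalization, death = death)
  if (any(rel < 0)) stop("relative SEs must be non-negative", call. = FALSE)
  structure(list(rel = rel, type = type), class = "mh_sd_model")
}

count_sd <- function(count, source, model, sumw2 = count) {
  rel <- model$rel[source]
  switch(model$type,
         relative = rel * count,
         design = sqrt(sumw2 + (rel * count)^2))
}

#' Tabulate weighted event counts by year, stratum, source, and category
#'
#' Sums record weights per cell and attaches the SD of each count under the
#' configured per-source variance model. The output grid is completed with
#' zero-count rows so that every (year, stratum) has exactly one entry per
#' source, as [combine_sources()] requires.
#'
#' @param records Classified, retained records (see [classify_events()],
#'   [apply_exclusions()]).
#' @param model An [sd_model()].
#' @param by_category If `TRUE`, counts are kept per event category;
#'   otherwise categories are rolled up.
#' @return Data frame of class `mh_counts` with columns `year`, `sex`,
#'   `age_group`, `source`, (`category`,) `count`, `sd`.
#' @export
tabulate_counts <- function(records, model = sd_model(), by_category = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("year", "sex", "age_group", "source", "weight")
  if (by_category) need <- c(need, "category")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop(sprintf("records are missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(records$weight < 0)) {
    stop("record weights must be non-negative", call. = FALSE)
  }
  keys <- c("year", "sex", "age_group", "source", if (by_category) "category")
  agg <- stats::aggregate(
    list(count = records$weight, sumw2 = records$weight^2),
    records[keys], sum)

  # complete the grid with explicit zeros
  grid <- expand.grid(
    year = sort(unique(records$year)), sex = mh_sexes(),
    age_group = mh_age_groups(), source = mh_sources(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  if (by_category) {
    grid <- merge(grid, data.frame(category = sort(unique(records$category)),
                                   stringsAsFactors = FALSE))
  }
  out <- merge(grid, agg, by = keys, all.x = TRUE, sort = TRUE)
  out$count[is.na(out$count)] <- 0
  out$sumw2[is.na(out$sumw2)] <- 0
  out$sd <- count_sd(out$count, out$source, model, out$sumw2)
  out <- out[do.call(order, out[keys]), c(keys, "count", "sd")]
  rownames(out) <- NULL
  class(out) <- c("mh_counts", "data.frame")
  out
}

#' Combine per-source counts into mutually exclusive event totals
#'
#' Sums the (already mutually exclusive) ED, hospitalization, and death counts
#' for each year and stratum and propagates the SDs assuming independence
#' across sources: `sd_total = sqrt(sum(sd^2))`.
#'
#' @param counts Data frame with columns `year`, `sex`, `age_group`,
#'   `source`, `count`, `sd` (optionally `category`; categories are summed
#'   within source first unless `by_category = TRUE`).
#' @param by_category Keep totals per event category instead of rolling up.
#' @return Data frame with columns `year`, `sex`, `age_group`,
#'   (`category`,) `count`, `sd`.
#' @examples
#' x <- data.frame(
#'   year = 2013, sex = "men", age_group = "45-64",
#'   source = c("ed", "hospitalization", "death"),
#'   count = c(343214, 2099874, 386073), sd = c(0, 0, 0)
#' )
#' combine_sources(x)$count  # 2829161
#' @export
combine_sources <- function(counts, by_category = FALSE) {
  stopifnot(is.data.frame(counts),
            all(c("year", "sex", "age_group", "source", "count", "sd")
                %in% names(counts)))
  keys <- c("year", "sex", "age_group", if (by_category) "category")
  if (by_category && !"category" %in% names(counts)) {
    stop("by_category = TRUE requires a 'category' column", call. = FALSE)
  }
  dup_keys <- c(keys, "source", if (!by_category && "category" %in% names(counts)) "category")
  if (anyDuplicated(counts[dup_keys])) {
    stop("duplicate source entries for the same year/stratum", call. = FALSE)
  }
  counts$var <- counts$sd^2
  agg <- stats::aggregate(counts[c("count", "var")], counts[keys], sum)
  agg$sd <- sqrt(agg$var)
  agg$var <- NULL
  agg <- agg[do.call(order, agg[keys]), c(keys, "count", "sd")]
  rownames(agg) <- NULL
  agg
}
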
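#' Surveillance strata
#'
#' Event rates are stratified by sex and adult age group. The four age groups
#' are disjoint and exhaust ages 18 and over, giving eight strata in all.
#'
#' @return `mh_strata()` returns a data frame with columns `sex` and
#'   `age_group`, one row per stratum (8 rows).
#' @examples
#' mh_strata()
#' @export
mh_strata <- function() {
  out <- expand.grid(
    age_group = mh_age_groups(),
    sex = mh_sexes(),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("sex", "age_group")]
  rownames(out) <- NULL
  out
}

#' @rdname mh_strata
#' @export
mh_sexes <- function() c("men", "women")

#' @rdname mh_strata
#' @export
mh_age_groups <- function() c("18-44", "45-64", "65-74", "75+")

#' @rdname mh_strata
#' @export
mh_sources <- function() c("ed", "hospitalization", "death")

# label used to key per-stratum vectors, e.g. "men:65-74"
stratum_key <- function(sex, age_group) paste(sex, age_group, sep = ":")

# validate that `x` is a per-stratum numeric vector (named by stratum key or
# positional in mh_strata() order); returns vector named by key
as_stratum_vector <- function(x, what) {
  st <- mh_strata()
  keys <- stratum_key(st$sex, st$age_group)
  if (length(x) == 1L) x <- rep(x, nrow(st))
  if (is.null(names(x))) {
    if (length(x) != nrow(st)) {
      stop(sprintf("'%s' must have length 1 or %d (one per stratum)",
                   what, nrow(st)), call. = FALSE)
    }
    names(x) <- keys
  } else {
    if (!all(keys %in% names(x))) {
      stop(sprintf("'%s' is missing strata: %s", what,
                   paste(setdiff(keys, names(x)), collapse = ", ")),
           call. = FALSE)
    }
    x <- x[keys]
  }
  x
}

# disposition flags recognised per source; deaths carry none
exclusion_flags <- function() {
  list(
    ed = c("died_in_facility", "transferred_out", "admitted_same_hospital"),
    hospitalization = c("elective", "died_in_facility", "transferred_out"),
    death = character(0)
  )
}

all_known_flags <- function() {
  unique(unlist(exclusion_flags(), use.names = FALSE))
}
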
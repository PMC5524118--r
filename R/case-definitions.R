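#' Case definitions for acute cardiovascular events
#'
#' An event is classified into one of four categories — acute myocardial
#' infarction (`ami`), `stroke`, `symptomatic_precursor` conditions, or
#' `other_cvd` — by prefix-matching its diagnosis code against configurable
#' code lists. ED and hospitalization records are matched on primary-diagnosis
#' codes (`ed_hosp_codes`, ICD-9-CM style); death records are matched on
#' underlying-cause-of-death codes (`death_codes`, ICD-10 style). Matching is
#' case-insensitive and ignores dots, so the pattern `"410"` matches
#' `"410.71"`.
#'
#' The default code lists shipped with the package
#' (`inst/extdata/case_definitions.yaml`) are a plausible editable starting
#' point, not an authoritative registry definition; surveillance deployments
#' are expected to supply their own YAML.
#'
#' @param path Path to a case-definition YAML file. The file maps
#'   `category -> subtype -> {ed_hosp_codes: [...], death_codes: [...]}`.
#' @return A data frame of class `mh_case_definitions` with columns
#'   `category`, `subtype`, `system` (one of `"ed_hosp"`, `"death"`), and
#'   `pattern`.
#' @examples
#' defs <- default_case_definitions()
#' head(defs)
#' @export
read_case_definitions <- function(path) {
  raw <- yaml::read_yaml(path)
  as_case_definitions(raw)
}

#' @rdname read_case_definitions
#' @export
default_case_definitions <- function() {
  read_case_definitions(
    system.file("extdata", "case_definitions.yaml", package = "heartsentinel",
                mustWork = TRUE)
  )
}

#' @rdname read_case_definitions
#' @param x A nested list as produced by reading the YAML layout above.
#' @export
as_case_definitions <- function(x) {
  categories <- c("ami", "stroke", "symptomatic_precursor", "other_cvd")
  rows <- list()
  for (cat in names(x)) {
    if (!cat %in% categories) {
      stop(sprintf("unknown event category '%s' in case definitions", cat),
           call. = FALSE)
    }
    for (sub in names(x[[cat]])) {
      entry <- x[[cat]][[sub]]
      for (system in c("ed_hosp", "death")) {
        codes <- entry[[paste0(system, "_codes")]]
        if (length(codes) == 0L) next
        codes <- as.character(unlist(codes, use.names = FALSE))
        if (any(!nzchar(codes))) {
          stop("empty code pattern in case definitions", call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, subtype = sub, system = system,
          pattern = codes, stringsAsFactors = FALSE
        )
      }
    }
  }
  defs <- do.call(rbind, rows)
  rownames(defs) <- NULL
  validate_case_definitions(defs)
  class(defs) <- c("mh_case_definitions", "data.frame")
  defs
}

# a normalized pattern may not belong to two categories within a code system
validate_case_definitions <- function(defs) {
  for (sys in unique(defs$system)) {
    d <- defs[defs$system == sys, ]
    norm <- normalize_code(d$pattern)
    dup <- norm[duplicated(norm)]
    if (length(dup)) {
      both <- unique(d$category[norm %in% dup])
      if (length(both) > 1L || anyDuplicated(paste(norm, d$category))) {
        stop(sprintf("code pattern(s) %s appear in more than one place in the %s system",
                     paste(unique(dup), collapse = ", "), sys), call. = FALSE)
      }
    }
  }
  invisible(defs)
}

# dot-stripped, upper-cased code normalization shared by matching and checks
normalize_code <- function(code) {
  toupper(gsub(".", "", code, fixed = TRUE))
}
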
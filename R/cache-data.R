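# Cache-fate data model: schema, validation, stage-conditional cohorts.

#' Column names of the cache-fate table
#'
#' The canonical CSV schema for a cache-fate table. One row per cache; counts
#' refer to seeds within the cache. Empty fields are nulls (not observed),
#' zero means observed-and-zero: a cache never located in year 1 has empty
#' year-1 fields, and a cache not relocated in year 2 has empty year-2 fields.
#'
#' @return Character vector of the fourteen mandatory column names.
#' @export
cache_columns <- function() {
  c("cache_id", "study_area", "elevation_zone", "microsite", "x", "y",
    "n_seeds_cached", "located_y1", "n_missing_y1", "n_seed_coats_y1",
    "n_germinants_y1", "relocated_y2", "n_live_seedlings_y2",
    "n_new_germinants_y2")
}

#' @keywords internal
canonical_microsite <- function(m) {
  m <- tolower(trimws(as.character(m)))
  m[m %in% c("no object", "no_object", "no-object", "none")] <- "open"
  m
}

#' @keywords internal
as_logical_field <- function(v) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes")] <- TRUE
  out[s %in% c("false", "f", "0", "no")] <- FALSE
  out[s %in% c("", "na")] <- NA
  bad <- !is.na(s) & s != "" & s != "na" &
    !s %in% c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad)) stop("unparseable logical value(s): ",
                     paste(unique(s[bad]), collapse = ", "), call. = FALSE)
  out
}

#' @keywords internal
as_count_field <- function(v, name) {
  if (is.numeric(v)) x <- v
  else {
    s <- trimws(as.character(v))
    s[s == "" | tolower(s) == "na"] <- NA
    x <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(x) & !is.na(s))
    if (length(bad)) stop("column '", name, "': non-numeric value in row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  nonint <- which(!is.na(x) & abs(x - round(x)) > 1e-8)
  if (length(nonint)) stop("column '", name, "': non-integer count in row(s) ",
                           paste(nonint, collapse = ", "), call. = FALSE)
  as.integer(round(x))
}

#' Validate a cache-fate table
#'
#' Checks the structural invariants of the cache-fate schema: unique ids,
#' recognised elevation-zone and microsite labels, at least one seed per
#' cache, non-negative counts, `n_missing_y1 + n_germinants_y1 <=
#' n_seeds_cached`, year-1 fields null (never zero) for caches not located in
#' year 1, and year-2 counts bounded by the year-1 state. Errors name the
#' offending `cache_id`s.
#'
#' @param records A data frame with the columns of [cache_columns()].
#' @return The validated table, invisibly, classed `cache_table`.
#' @export
validate_cache_table <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(cache_columns(), names(records))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  r <- records
  errs <- character(0)
  add <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      ids <- r$cache_id[which(bad)]
      errs <<- c(errs, paste0(msg, " [cache_id: ",
                              paste(utils::head(ids, 5), collapse = ", "),
                              if (sum(bad, na.rm = TRUE) > 5) ", ..." else "",
                              "]"))
    }
  }
  if (anyDuplicated(r$cache_id))
    errs <- c(errs, paste0("duplicated cache_id: ",
                           paste(unique(r$cache_id[duplicated(r$cache_id)]),
                                 collapse = ", ")))
  add(!r$elevation_zone %in% c("subalpine", "treeline"),
      "elevation_zone must be 'subalpine' or 'treeline'")
  add(!r$microsite %in% c("rock", "tree", "open"),
      "microsite must be 'rock', 'tree' or 'open'/'no object'")
  add(is.na(r$x) | is.na(r$y), "coordinates must be non-missing planar meters")
  add(is.na(r$n_seeds_cached) | r$n_seeds_cached < 1L,
      "n_seeds_cached must be >= 1")
  for (col in c("n_missing_y1", "n_seed_coats_y1", "n_germinants_y1",
                "n_live_seedlings_y2", "n_new_germinants_y2"))
    add(!is.na(r[[col]]) & r[[col]] < 0L, paste0(col, " must be >= 0"))
  add(is.na(r$located_y1), "located_y1 must be TRUE or FALSE")
  loc <- !is.na(r$located_y1) & r$located_y1
  add(loc & (is.na(r$n_missing_y1) | is.na(r$n_germinants_y1)),
      "located caches need observed n_missing_y1 and n_germinants_y1")
  add(!loc & (!is.na(r$n_missing_y1) | !is.na(r$n_germinants_y1) |
                !is.na(r$n_seed_coats_y1)),
      "caches not located in year 1 must have empty year-1 fields")
  add(loc & !is.na(r$n_missing_y1) & !is.na(r$n_germinants_y1) &
        r$n_missing_y1 + r$n_germinants_y1 > r$n_seeds_cached,
      "n_missing_y1 + n_germinants_y1 exceeds n_seeds_cached")
  add(!is.na(r$n_live_seedlings_y2) & !is.na(r$n_germinants_y1) &
        r$n_live_seedlings_y2 > r$n_germinants_y1,
      "n_live_seedlings_y2 exceeds n_germinants_y1")
  reloc_false <- !is.na(r$relocated_y2) & !r$relocated_y2
  add(reloc_false & (!is.na(r$n_live_seedlings_y2) |
                       !is.na(r$n_new_germinants_y2)),
      "caches not relocated in year 2 must have empty year-2 fields")
  if (length(errs))
    stop("cache table validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  class(r) <- unique(c("cache_table", class(r)))
  invisible(r)
}

#' Read a cache-fate table from CSV
#'
#' Column headers are matched case-insensitively; the microsite spelling
#' "no object" (or "no_object") is accepted and canonicalised to "open".
#' Unparseable rows are reported with their row numbers, and validation
#' errors name the offending caches.
#'
#' @param path Path to a CSV file with the columns of [cache_columns()].
#' @return A `cache_table` data frame.
#' @seealso [write_cache_table()], [validate_cache_table()]
#' @export
read_cache_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(cache_columns(), names(raw))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  r <- raw[cache_columns()]
  r$cache_id <- trimws(r$cache_id)
  r$study_area <- trimws(r$study_area)
  r$elevation_zone <- tolower(trimws(r$elevation_zone))
  r$microsite <- canonical_microsite(r$microsite)
  for (col in c("x", "y")) {
    s <- trimws(r[[col]])
    s[s == ""] <- NA
    x <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(x) & !is.na(s))
    if (length(bad)) stop("column '", col, "': non-numeric value in row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    r[[col]] <- x
  }
  for (col in c("n_seeds_cached", "n_missing_y1", "n_seed_coats_y1",
                "n_germinants_y1", "n_live_seedlings_y2",
                "n_new_germinants_y2"))
    r[[col]] <- as_count_field(r[[col]], col)
  r$located_y1 <- as_logical_field(r$located_y1)
  r$relocated_y2 <- as_logical_field(r$relocated_y2)
  validate_cache_table(r)
}

#' Write a cache-fate table to CSV
#'
#' Inverse of [read_cache_table()]: writing then re-reading a valid table is
#' the identity on records. Nulls are written as empty fields.
#'
#' @param records A validated `cache_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cache_table <- function(records, path) {
  records <- validate_cache_table(records)
  out <- as.data.frame(records)[cache_columns()]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive stage outcomes for located caches
#'
#' Computes per-cache stage flags from the raw counts. A cache is *pilfered*
#' if at least one seed went missing in year 1. It is eligible for the
#' germination analysis if at least one intact seed remained after pilferage
#' and/or it already had a first-year seedling. It is eligible for the
#' survival analysis if it had one or more first-year seedlings, and a
#' survivor is a cache with one or more live seedlings in year 2. Two-year
#' germination success means germination in year 1 or year 2; its
#' denominator requires relocation in year 2 (unobserved caches drop out).
#'
#' @param records A `cache_table` (or compatible data frame) in which every
#'   row was located in year 1; caches never located are excluded from all
#'   cohorts and calling this on them is an error.
#' @return A data frame with one row per record: `cache_id`, `pilfered`,
#'   `eligible_germination`, `germinated_y1`, `eligible_survival`,
#'   `survived_y2`, `eligible_two_year`, `germinated_two_year`. Flags that
#'   cannot be evaluated because year-2 observation is missing are `NA`.
#' @export
derive_outcomes <- function(records) {
  r <- as.data.frame(records)
  if (any(is.na(r$located_y1)) || !all(r$located_y1))
    stop("derive_outcomes() applies only to caches located in year 1; ",
         "caches never located are excluded from every cohort", call. = FALSE)
  pilfered <- r$n_missing_y1 >= 1L
  intact <- r$n_seeds_cached - r$n_missing_y1
  germinated_y1 <- r$n_germinants_y1 >= 1L
  eligible_germination <- intact >= 1L | germinated_y1
  eligible_survival <- germinated_y1
  survived_y2 <- ifelse(eligible_survival,
                        ifelse(is.na(r$n_live_seedlings_y2), NA,
                               r$n_live_seedlings_y2 >= 1L),
                        FALSE)
  relocated <- !is.na(r$relocated_y2) & r$relocated_y2
  eligible_two_year <- eligible_germination & relocated
  germinated_two_year <- ifelse(germinated_y1, TRUE,
                                ifelse(is.na(r$n_new_germinants_y2), NA,
                                       r$n_new_germinants_y2 >= 1L))
  data.frame(cache_id = r$cache_id, pilfered = pilfered,
             eligible_germination = eligible_germination,
             germinated_y1 = germinated_y1,
             eligible_survival = eligible_survival,
             survived_y2 = survived_y2,
             eligible_two_year = eligible_two_year,
             germinated_two_year = germinated_two_year,
             stringsAsFactors = FALSE)
}

#' @keywords internal
stage_levels <- function() {
  c("pilferage", "germination_y1", "survival", "germination_2yr")
}

#' Build a stage-conditional cohort
#'
#' Cohort sizes differ by life stage because germination and survival are
#' conditional on surviving the previous stage: the pilferage cohort is every
#' cache located in year 1; the year-1 germination cohort is every cache with
#' one or more intact seeds after pilferage and/or a first-year seedling; the
#' survival cohort is every cache with one or more first-year seedlings; and
#' the two-year germination cohort is the germination cohort restricted to
#' caches relocated in year 2.
#'
#' @param records A `cache_table`.
#' @param stage One of `"pilferage"`, `"germination_y1"`, `"survival"`,
#'   `"germination_2yr"`.
#' @param filter Optional stratum restriction: a named list such as
#'   `list(elevation_zone = "treeline")`, a logical vector over `records`,
#'   or a predicate function taking the records and returning a logical
#'   vector.
#' @return A `stage_cohort`: a data frame of `cache_id`, the stratum labels,
#'   coordinates and a logical `success` column, with the stage in
#'   `attr(, "stage")`. An empty cohort is returned (with a warning) as a
#'   zero-row cohort so that callers can decide how to fail.
#' @export
build_cohort <- function(records, stage = stage_levels(), filter = NULL) {
  stage <- match.arg(stage)
  r <- as.data.frame(records)
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) filter(r)
    else if (is.logical(filter)) filter
    else if (is.list(filter)) {
      k <- rep(TRUE, nrow(r))
      for (nm in names(filter)) {
        if (!nm %in% names(r)) stop("unknown filter column: ", nm, call. = FALSE)
        k <- k & r[[nm]] %in% filter[[nm]]
      }
      k
    } else stop("filter must be a named list, logical vector or function",
                call. = FALSE)
    r <- r[keep, , drop = FALSE]
  }
  r <- r[!is.na(r$located_y1) & r$located_y1, , drop = FALSE]
  if (nrow(r) == 0L) {
    warning("empty cohort for stage '", stage, "'", call. = FALSE)
    return(empty_cohort(stage))
  }
  o <- derive_outcomes(r)
  eligible <- switch(stage,
    pilferage = rep(TRUE, nrow(r)),
    germination_y1 = o$eligible_germination,
    survival = o$eligible_survival,
    germination_2yr = o$eligible_two_year)
  success <- switch(stage,
    pilferage = o$pilfered,
    germination_y1 = o$germinated_y1,
    survival = o$survived_y2,
    germination_2yr = o$germinated_two_year)
  keep <- eligible & !is.na(success)
  dropped <- sum(eligible & is.na(success))
  if (dropped > 0L)
    message(dropped, " eligible cache(s) dropped from '", stage,
            "' cohort: year-2 outcome unobserved")
  cohort <- data.frame(cache_id = r$cache_id[keep],
                       study_area = r$study_area[keep],
                       elevation_zone = r$elevation_zone[keep],
                       microsite = r$microsite[keep],
                       x = r$x[keep], y = r$y[keep],
                       success = success[keep],
                       stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L)
    warning("empty cohort for stage '", stage, "'", call. = FALSE)
  attr(cohort, "stage") <- stage
  class(cohort) <- unique(c("stage_cohort", class(cohort)))
  cohort
}

#' @keywords internal
empty_cohort <- function(stage) {
  cohort <- data.frame(cache_id = character(0), study_area = character(0),
                       elevation_zone = character(0), microsite = character(0),
                       x = numeric(0), y = numeric(0), success = logical(0),
                       stringsAsFactors = FALSE)
  attr(cohort, "stage") <- stage
  class(cohort) <- unique(c("stage_cohort", class(cohort)))
  cohort
}

#' @export
print.stage_cohort <- function(x, ...) {
  cat("Stage cohort:", attr(x, "stage"), "\n")
  cat("  caches:", nrow(x), "  successes:", sum(x$success), "\n")
  invisible(x)
}
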
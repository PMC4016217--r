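# Reading, validating and normalizing the three survey-table dialects, and
# construction of per-site occupancy series.

#' Default substrate synonym map
#'
#' Reads the synonym table shipped with the package
#' (`extdata/substrate-synonyms.csv`).  Each row maps a lower-case label as
#' found in archives ("cattails", "tule", "silage", ...) to a canonical
#' substrate from [substrate_levels()].  Users can extend or replace the map
#' by passing their own two-column data frame (`pattern`, `canonical`) to the
#' readers, so new archive dialects need no code change.
#'
#' @return data.frame with columns `pattern` and `canonical`.
#' @export
default_substrate_synonyms <- function() {
  path <- system.file("extdata", "substrate-synonyms.csv", package = "habvalue")
  if (!nzchar(path)) stop("synonym table not found; is habvalue installed?")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Normalize substrate labels
#'
#' Case-insensitive lookup in a synonym map; labels without a match are kept
#' as trimmed lower-case free-form categories rather than dropped, so rare
#' substrates (e.g. *Arundo*, mesquite) stay visible to the minimum-records
#' filters downstream.
#'
#' @param x character vector of raw substrate labels.
#' @param synonyms synonym map, see [default_substrate_synonyms()].
#' @return character vector of normalized labels.
#' @export
normalize_substrate <- function(x, synonyms = default_substrate_synonyms()) {
  key <- tolower(trimws(as.character(x)))
  idx <- match(key, tolower(synonyms$pattern))
  out <- ifelse(is.na(idx), key, synonyms$canonical[idx])
  out[!nzchar(out)] <- NA_character_
  out
}

.schema_columns <- list(
  portal    = c("site_id", "year", "substrate", "status",
                "n_breeding_birds", "n_nests", "n_fledglings"),
  hamilton  = c("colony_id", "year", "substrate", "n_breeding_birds",
                "n_fledglings", "rss", "prop_successful"),
  statewide = c("record_id", "year", "substrate", "n_birds")
)

.empty_records <- function() {
  data.frame(site_id = character(), year = integer(), substrate = character(),
             status = character(), n_breeding_birds = numeric(),
             n_nests = numeric(), n_fledglings = numeric(), rss = numeric(),
             prop_successful = numeric(), dataset_tag = character(),
             stringsAsFactors = FALSE)
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a survey table
#'
#' Parses one of the three supported comma-separated survey dialects into a
#' normalized record table.  The three schemas are:
#' \describe{
#'   \item{portal}{`site_id, year, substrate, status, n_breeding_birds,
#'     n_nests, n_fledglings` -- occupancy plus reproduction, one row per
#'     site visit or site-year.  A blank/missing status means the site was
#'     not surveyed that year and is coded `"unknown"`.}
#'   \item{hamilton}{`colony_id, year, substrate, n_breeding_birds,
#'     n_fledglings, rss, prop_successful` -- reproduction records; status is
#'     `"occupied"` by construction.}
#'   \item{statewide}{`record_id, year, substrate, n_birds` -- colony
#'     records used for decadal frequency and size summaries.}
#' }
#'
#' Multiple within-season rows for the same site and year are collapsed to
#' one annual record: the site is occupied if any visit found breeding
#' birds, unoccupied if it was visited and none were ever found, else
#' unknown; counts take the per-year maximum (the seasonal peak estimate).
#' Exactly duplicated rows are dropped and counted.  Rows whose year or
#' counts cannot be parsed are skipped and counted.  A `validation`
#' attribute (see [validation_report()]) records what happened.
#'
#' @param path path to a CSV file with a header row (UTF-8).
#' @param schema one of `"portal"`, `"hamilton"`, `"statewide"`.
#' @param synonyms substrate synonym map; see [default_substrate_synonyms()].
#' @param study_window inclusive year range accepted as valid.
#' @return data.frame of class `"survey_records"` with columns `site_id`,
#'   `year`, `substrate`, `status`, `n_breeding_birds`, `n_nests`,
#'   `n_fledglings`, `rss`, `prop_successful`, `dataset_tag`.
#' @export
read_survey_table <- function(path,
                              schema = c("portal", "hamilton", "statewide"),
                              synonyms = default_substrate_synonyms(),
                              study_window = c(1980L, 2011L)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- .schema_columns[[schema]]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema '%s' requires column(s): %s", schema,
                 paste(missing_cols, collapse = ", ")))
  }
  n_in <- nrow(raw)
  issues <- list()

  year <- suppressWarnings(as.integer(raw$year))
  bad_year <- is.na(year) | year < study_window[1] | year > study_window[2]
  if (any(bad_year)) issues$year <- sum(bad_year)

  id_col <- switch(schema, portal = "site_id", hamilton = "colony_id",
                   statewide = "record_id")
  site_id <- trimws(raw[[id_col]])
  bad_id <- !nzchar(site_id) | is.na(site_id)
  if (any(bad_id)) issues$site_id <- sum(bad_id)

  keep <- !(bad_year | bad_id)
  n_unparseable <- sum(!keep)

  rec <- .empty_records()
  if (any(keep)) {
    raw <- raw[keep, , drop = FALSE]
    rec <- data.frame(
      site_id = site_id[keep],
      year = year[keep],
      substrate = normalize_substrate(raw$substrate, synonyms),
      status = NA_character_,
      n_breeding_birds = NA_real_, n_nests = NA_real_,
      n_fledglings = NA_real_, rss = NA_real_, prop_successful = NA_real_,
      dataset_tag = schema,
      stringsAsFactors = FALSE
    )
    if (schema == "portal") {
      st <- tolower(trimws(raw$status))
      st[!nzchar(st) | is.na(st)] <- "unknown"
      bad_status <- !(st %in% .status_levels)
      if (any(bad_status)) {
        issues$status <- sum(bad_status)
        st[bad_status] <- "unknown"
      }
      rec$status <- st
      rec$n_breeding_birds <- .num_or_na(raw$n_breeding_birds)
      rec$n_nests <- .num_or_na(raw$n_nests)
      rec$n_fledglings <- .num_or_na(raw$n_fledglings)
    } else if (schema == "hamilton") {
      rec$status <- "occupied"
      rec$n_breeding_birds <- .num_or_na(raw$n_breeding_birds)
      rec$n_fledglings <- .num_or_na(raw$n_fledglings)
      rec$rss <- .num_or_na(raw$rss)
      rec$prop_successful <- .num_or_na(raw$prop_successful)
    } else {
      rec$status <- "occupied"
      rec$n_breeding_birds <- .num_or_na(raw$n_birds)
    }
    neg <- c("n_breeding_birds", "n_nests", "n_fledglings")
    for (col in neg) {
      bad <- !is.na(rec[[col]]) & rec[[col]] < 0
      if (any(bad)) {
        issues[[col]] <- sum(bad)
        rec[[col]][bad] <- NA_real_
      }
    }
  }

  n_before <- nrow(rec)
  rec <- unique(rec)
  n_dup <- n_before - nrow(rec)
  rec <- .collapse_visits(rec)
  rec <- rec[order(rec$site_id, rec$year), , drop = FALSE]
  rownames(rec) <- NULL

  attr(rec, "validation") <- validation_report(
    n_records = nrow(rec), n_duplicates_dropped = n_dup,
    n_unparseable = n_unparseable, issues = issues, n_input_rows = n_in)
  class(rec) <- c("survey_records", "data.frame")
  rec
}

# Collapse within-season visit rows to one annual record per
# (site, year, dataset_tag): occupied if any visit was, else unoccupied if
# any visit was, else unknown; counts take the seasonal maximum.
.collapse_visits <- function(rec) {
  if (nrow(rec) == 0L) return(rec)
  key <- paste(rec$site_id, rec$year, rec$dataset_tag, sep = "\r")
  if (!anyDuplicated(key)) return(rec)
  pieces <- split(rec, key)
  out <- lapply(pieces, function(g) {
    if (nrow(g) == 1L) return(g)
    st <- if (any(g$status == "occupied")) "occupied"
          else if (any(g$status == "unoccupied")) "unoccupied" else "unknown"
    r <- g[1L, , drop = FALSE]
    r$status <- st
    sub <- unique(na.omit(g$substrate))
    r$substrate <- if (length(sub) > 0L) sub[1L] else NA_character_
    for (col in c("n_breeding_birds", "n_nests", "n_fledglings",
                  "rss", "prop_successful")) {
      v <- g[[col]]
      r[[col]] <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build a validation report
#'
#' Bookkeeping for [read_survey_table()]: how many rows were parsed,
#' deduplicated or skipped, with per-field issue counts.
#'
#' @param n_records rows in the parsed table.
#' @param n_duplicates_dropped exactly duplicated rows removed.
#' @param n_unparseable rows skipped (bad year or id).
#' @param issues named list of per-field issue counts.
#' @param n_input_rows rows in the raw file.
#' @return list of class `"validation_report"`.
#' @export
validation_report <- function(n_records, n_duplicates_dropped = 0L,
                              n_unparseable = 0L, issues = list(),
                              n_input_rows = n_records) {
  stopifnot(n_records >= 0, n_duplicates_dropped >= 0, n_unparseable >= 0)
  structure(list(n_records = n_records,
                 n_duplicates_dropped = n_duplicates_dropped,
                 n_unparseable = n_unparseable,
                 issues = issues,
                 n_input_rows = n_input_rows),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Survey table validation:", x$n_records, "records from",
      x$n_input_rows, "rows;", x$n_duplicates_dropped, "duplicates dropped;",
      x$n_unparseable, "unparseable rows skipped\n")
  if (length(x$issues) > 0L) {
    for (nm in names(x$issues)) cat("  issue:", nm, "->", x$issues[[nm]], "\n")
  }
  invisible(x)
}

#' Write survey records or occupancy series to the portal schema
#'
#' Inverse of [read_survey_table()] for the portal dialect; used for
#' round-trip checks and for exporting normalized data.  Unknown years are
#' written with a blank status, matching the convention that an unsurveyed
#' site-year carries no information.
#'
#' @param x a `survey_records` or `occupancy_series` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(x, path) {
  if (inherits(x, "occupancy_series")) {
    out <- data.frame(site_id = x$site_id, year = x$year,
                      substrate = x$substrate, status = x$status,
                      n_breeding_birds = NA_real_, n_nests = NA_real_,
                      n_fledglings = NA_real_, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(site_id = x$site_id, year = x$year,
                      substrate = x$substrate, status = x$status,
                      n_breeding_birds = x$n_breeding_birds,
                      n_nests = x$n_nests, n_fledglings = x$n_fledglings,
                      stringsAsFactors = FALSE)
  }
  out$status[out$status == "unknown"] <- ""
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build per-site occupancy series
#'
#' Turns validated survey records into annual occupancy series, one per site
#' (split into separate series when a site's recorded substrate changes, so
#' turnover and longevity stay substrate-specific).  Within each site's
#' observed span, years with no record become `"unknown"`; years outside the
#' span are absent entirely, because nothing bounds them.
#'
#' Conflicting statuses for the same site and year (possible when several
#' datasets are combined) are a hard error: silent resolution would bias the
#' turnover denominators.
#'
#' @param records a `survey_records` data frame (rows with status `NA` are
#'   treated as unknown).
#' @return data.frame of class `"occupancy_series"` with columns
#'   `series_id`, `site_id`, `substrate`, `year`, `status`, one row per
#'   series-year, years consecutive within each series.
#' @export
build_occupancy_series <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- data.frame(series_id = character(), site_id = character(),
                      substrate = character(), year = integer(),
                      status = character(), stringsAsFactors = FALSE)
    class(out) <- c("occupancy_series", "data.frame")
    return(out)
  }
  rec <- as.data.frame(records)
  rec$status[is.na(rec$status)] <- "unknown"

  key <- paste(rec$site_id, rec$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- split(rec, key)
    for (g in dup) {
      st <- unique(g$status[g$status != "unknown"])
      if (length(st) > 1L) {
        stop(sprintf(
          "conflicting statuses for site '%s' in year %d: %s",
          g$site_id[1], g$year[1], paste(sort(st), collapse = " vs ")))
      }
    }
    # statuses agree; merge keeping the informative one
    rec <- do.call(rbind, lapply(dup, function(g) {
      r <- g[order(match(g$status, .status_levels))[1L], , drop = FALSE]
      sub <- unique(na.omit(g$substrate))
      r$substrate <- if (length(sub) > 0L) sub[1L] else NA_character_
      r
    }))
  }

  pieces <- split(rec, rec$site_id)
  out <- vector("list", 0L)
  for (g in pieces) {
    g <- g[order(g$year), , drop = FALSE]
    # split into runs of constant substrate over surveyed years; unknown
    # substrate inherits the previous surveyed value within the site
    sub <- g$substrate
    for (i in seq_along(sub)) {
      if (is.na(sub[i]) && i > 1L) sub[i] <- sub[i - 1L]
    }
    for (i in rev(seq_along(sub))) {
      if (is.na(sub[i]) && i < length(sub)) sub[i] <- sub[i + 1L]
    }
    run <- cumsum(c(TRUE, sub[-1L] != sub[-length(sub)]))
    for (r in unique(run)) {
      gi <- g[run == r, , drop = FALSE]
      yrs <- seq(min(gi$year), max(gi$year))
      status <- rep("unknown", length(yrs))
      status[match(gi$year, yrs)] <- gi$status
      sid <- gi$site_id[1L]
      series_id <- if (length(unique(run)) == 1L) sid else
        paste0(sid, "#", r)
      out[[length(out) + 1L]] <- data.frame(
        series_id = series_id, site_id = sid,
        substrate = sub[run == r][1L], year = yrs, status = status,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$series_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occupancy_series", "data.frame")
  out
}
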
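# Reading and writing Darwin-Core-style occurrence tables, taxon lookup
# tables, gazetteers and synthetic country rectangles. Every downstream
# module consumes the canonical tibble produced here.

#' Canonical occurrence columns
#'
#' Internal column names follow Darwin Core terms where one exists. All
#' readers coerce to these names; [read_occurrences()]'s `field_map` handles
#' other dialects.
#'
#' @return Character vector of canonical column names.
#' @export
occ_columns <- function() {
  c("record_id", "scientificName", "decimalLatitude", "decimalLongitude",
    "countryCode", "eventDate", "year", "basisOfRecord", "recordedBy",
    "datasetName", "taxonRank")
}

# everything is read as character; numeric parsing happens afterwards so
# unparseable values can be flagged instead of silently coerced
.occ_col_types <- readr::cols(.default = readr::col_character())

#' Read an occurrence table
#'
#' Reads a CSV/TSV occurrence file into the canonical tibble. Unparseable
#' numeric coordinates and years become `NA` and are flagged in the attached
#' read report; no row is ever dropped silently
#' (`rows_in = rows_parsed + rows_flagged`).
#'
#' @param path file path; delimiter inferred from the extension (`.tsv` /
#'   `.txt` read as tab) unless `delim` is given.
#' @param field_map optional named character vector mapping file columns to
#'   canonical fields, e.g. `c(lat = "decimalLatitude")`. Columns already
#'   canonically named need no entry. Must cover at least `scientificName`,
#'   `decimalLatitude` and `decimalLongitude`.
#' @param delim optional explicit delimiter.
#' @return A tibble with the columns of [occ_columns()] and attribute
#'   `read_report` (a list with `rows_in`, `rows_parsed`, `rows_flagged` and
#'   an `issues` tibble).
#' @export
read_occurrences <- function(path, field_map = NULL, delim = NULL) {
  stopifnot(file.exists(path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = .occ_col_types,
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  raw[raw == ""] <- NA
  if (!is.null(field_map)) {
    bad <- setdiff(names(field_map), names(raw))
    if (length(bad) > 0) {
      stop("field_map names columns absent from the file: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    names(raw)[match(names(field_map), names(raw))] <- unname(field_map)
  }
  mandatory <- c("scientificName", "decimalLatitude", "decimalLongitude")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("mandatory column(s) not present after field_map: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(occ_columns(), names(raw))) raw[[col]] <- NA_character_
  out <- raw[occ_columns()]

  issues <- list()
  flag <- function(rows, field, reason) {
    if (length(rows) > 0) {
      issues[[length(issues) + 1]] <<- tibble::tibble(
        row = rows, field = field, reason = reason)
    }
  }
  num <- function(field, lo, hi) {
    x <- out[[field]]
    v <- suppressWarnings(as.numeric(x))
    flag(which(!is.na(x) & is.na(v)), field, "unparseable")
    flag(which(!is.na(v) & (v < lo | v > hi)), field, "out_of_range")
    v
  }
  out$decimalLatitude <- num("decimalLatitude", -90, 90)
  out$decimalLongitude <- num("decimalLongitude", -180, 180)
  yr <- suppressWarnings(as.integer(out$year))
  flag(which(!is.na(out$year) & is.na(yr)), "year", "unparseable")
  out$year <- yr
  # year, when present, must equal the year component of a parseable eventDate
  ed_year <- suppressWarnings(as.integer(substr(out$eventDate, 1, 4)))
  flag(which(!is.na(out$year) & !is.na(ed_year) & out$year != ed_year),
       "year", "disagrees_with_eventDate")
  if (any(is.na(out$record_id))) {
    out$record_id <- ifelse(is.na(out$record_id),
                            sprintf("rec%07d", seq_len(nrow(out))),
                            out$record_id)
  }
  if (anyDuplicated(out$record_id)) {
    stop("record_id values are not unique", call. = FALSE)
  }
  issues <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble::tibble(row = integer(), field = character(), reason = character())
  report <- list(rows_in = nrow(raw),
                 rows_parsed = nrow(out) - length(unique(issues$row)),
                 rows_flagged = length(unique(issues$row)),
                 issues = issues)
  if (nrow(out) == 0) warning("empty occurrence file: ", path, call. = FALSE)
  attr(out, "read_report") <- report
  out
}

#' Write an occurrence table
#'
#' Writes the canonical CSV dialect (UTF-8, header, RFC-4180 quoting,
#' missing values as empty strings). `read_occurrences(write_occurrences(x))`
#' reproduces `x` field for field.
#'
#' @param records canonical occurrence tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  stopifnot(all(occ_columns() %in% names(records)))
  readr::write_csv(records[occ_columns()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a taxonomic lookup table
#'
#' A lookup maps raw name strings to accepted binomials for one
#' standardisation source. Input CSV columns: `raw_name`, `accepted_name`,
#' `status` (one of accepted, synonym, unresolved, no_match) and optionally
#' `source_label`. Raw names are normalised with [normalise_name()] for
#' matching; duplicate raw names pointing at different accepted names are a
#' validation error.
#'
#' @param path CSV file path.
#' @param source_label label for the source; defaults to the file's
#'   `source_label` column or the file name.
#' @param match_policy `"exact"` or `"fuzzy"` (edit distance at most
#'   `max_distance`).
#' @param max_distance maximum edit distance for fuzzy matching.
#' @return A `taxon_lookup` object.
#' @export
read_taxon_lookup <- function(path, source_label = NULL,
                              match_policy = c("exact", "fuzzy"),
                              max_distance = 1) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       na = character(), progress = FALSE,
                       show_col_types = FALSE)
  need <- c("raw_name", "accepted_name", "status")
  if (!all(need %in% names(x))) {
    stop("lookup file must have columns raw_name, accepted_name, status",
         call. = FALSE)
  }
  if (is.null(source_label)) {
    source_label <- if ("source_label" %in% names(x) && any(x$source_label != ""))
      x$source_label[x$source_label != ""][1] else basename(path)
  }
  x$accepted_name[x$accepted_name == ""] <- NA_character_
  taxon_lookup(x[need], source_label = source_label,
               match_policy = match.arg(match_policy),
               max_distance = max_distance)
}

#' Construct a taxon lookup from a table
#'
#' @param entries data frame with `raw_name`, `accepted_name` (may be `NA`
#'   for unresolved/no_match rows) and `status`.
#' @inheritParams read_taxon_lookup
#' @return A `taxon_lookup` object: the entry table keyed on the normalised
#'   raw name, plus the match policy.
#' @export
taxon_lookup <- function(entries, source_label,
                         match_policy = c("exact", "fuzzy"),
                         max_distance = 1) {
  match_policy <- match.arg(match_policy)
  entries <- tibble::as_tibble(entries)
  ok_status <- c("accepted", "synonym", "unresolved", "no_match")
  bad <- setdiff(unique(entries$status), ok_status)
  if (length(bad) > 0) {
    stop("invalid status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  entries$raw_norm <- normalise_name(entries$raw_name)
  entries <- dplyr::distinct(entries, .data$raw_norm, .data$accepted_name,
                             .data$status, .keep_all = TRUE)
  conf <- entries |>
    dplyr::filter(!is.na(.data$accepted_name)) |>
    dplyr::distinct(.data$raw_norm, .data$accepted_name) |>
    dplyr::count(.data$raw_norm) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conf) > 0) {
    stop("conflicting accepted names for raw name(s): ",
         paste(conf$raw_norm, collapse = ", "), call. = FALSE)
  }
  # a resolved row wins over an unresolved duplicate of the same raw name
  entries <- entries |>
    dplyr::arrange(.data$raw_norm, is.na(.data$accepted_name)) |>
    dplyr::distinct(.data$raw_norm, .keep_all = TRUE)
  structure(list(source_label = source_label,
                 entries = entries,
                 match_policy = match_policy,
                 max_distance = max_distance),
            class = "taxon_lookup")
}

#' @export
print.taxon_lookup <- function(x, ...) {
  cat("<taxon_lookup> ", x$source_label, ": ", nrow(x$entries),
      " entries, match ", x$match_policy, "\n", sep = "")
  invisible(x)
}

#' Write a taxon lookup table to CSV
#' @param lookup a `taxon_lookup`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_taxon_lookup <- function(lookup, path) {
  out <- lookup$entries[c("raw_name", "accepted_name", "status")]
  out$source_label <- lookup$source_label
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a gazetteer of suspect localities
#'
#' Country centroids, institution and repository-headquarter coordinates near
#' which records are considered unreliable. CSV columns: `label`, `lat`,
#' `lon`, `radius_km`, `kind` (country_centroid, institution,
#' repository_hq).
#'
#' @param path CSV file path.
#' @return A tibble; `radius_km` must be positive.
#' @export
read_gazetteer <- function(path) {
  g <- readr::read_csv(path, col_types = "cdddc", na = character(),
                       progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("label", "lat", "lon", "radius_km", "kind") %in% names(g)))
  if (any(g$radius_km <= 0)) stop("radius_km must be > 0", call. = FALSE)
  g
}

#' Read a country-rectangle table
#'
#' Countries are modelled as axis-aligned longitude/latitude rectangles so
#' the country-mismatch filter is exactly checkable without polygon data.
#' CSV columns: `countryCode`, `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#'
#' @param path CSV file path.
#' @return A tibble with the rectangle bounds plus centroid columns.
#' @export
read_countries <- function(path) {
  x <- readr::read_csv(path, col_types = "cdddd", na = character(),
                       progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("countryCode", "lon_min", "lon_max", "lat_min", "lat_max")
                %in% names(x)))
  x$centroid_lon <- (x$lon_min + x$lon_max) / 2
  x$centroid_lat <- (x$lat_min + x$lat_max) / 2
  x
}
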
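# Record-level exclusion rules applied before any analysis: fossil records,
# illegitimate collection dates, suspect coordinates, country mismatches,
# gazetteer proximity, and taxonomic rank; then assignment of the surviving
# records to equal-area grid cells, latitudinal bands and regions.
#
# Every filter returns a partition of its input: list(kept, removed, report),
# with kept + removed == input row-for-row.

.filter_result <- function(records, drop, report) {
  drop[is.na(drop)] <- FALSE
  list(kept = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       report = report)
}

.rule_report <- function(...) {
  x <- c(...)
  tibble::tibble(rule = names(x), n_flagged = as.integer(x))
}

#' Remove fossil records
#'
#' Drops records whose `basisOfRecord` is FossilSpecimen (matched
#' case/format-insensitively).
#'
#' @param records canonical occurrence tibble.
#' @return List with `kept`, `removed` and a per-rule `report`.
#' @export
filter_fossil <- function(records) {
  drop <- .norm_basis(records$basisOfRecord) == "FOSSILSPECIMEN"
  .filter_result(records, drop, .rule_report(fossil = sum(drop, na.rm = TRUE)))
}

.norm_basis <- function(x) toupper(gsub("[^A-Za-z]", "", x))

#' Remove records with illegitimate collection dates
#'
#' A date is illegitimate when it is present but not a real calendar date
#' (e.g. month 13), or when the stated year lies in the future. Records with
#' no date information at all are kept: absence of a date is missing
#' metadata, not an error, and undated records are handled by the temporal
#' filters downstream.
#'
#' @param records canonical occurrence tibble.
#' @param max_year latest legitimate year (default: the current year).
#' @return List with `kept`, `removed` and `report`.
#' @export
filter_dates <- function(records,
                         max_year = as.integer(format(Sys.Date(), "%Y"))) {
  ed <- records$eventDate
  parsed <- as.Date(rep(NA_character_, length(ed)))
  has_ed <- !is.na(ed)
  if (any(has_ed)) {
    parsed[has_ed] <- suppressWarnings(
      as.Date(ed[has_ed], tryFormats = c("%Y-%m-%d", "%Y/%m/%d", "%d/%m/%Y"),
              optional = TRUE))
  }
  bad_format <- has_ed & is.na(parsed)
  ed_year <- as.integer(format(parsed, "%Y"))
  future <- (!is.na(records$year) & records$year > max_year) |
    (!is.na(ed_year) & ed_year > max_year)
  drop <- bad_format | future
  .filter_result(records, drop,
                 .rule_report(invalid_date = sum(bad_format, na.rm = TRUE),
                              future_date = sum(future, na.rm = TRUE)))
}

#' Remove records with suspect coordinates
#'
#' Drops records with (a) latitude exactly equal to longitude, (b) a zero
#' coordinate, (c) both coordinates integral (no decimal digits), (d)
#' missing coordinates, or (e) latitude south of the study limit. By
#' default the zero rule fires when either coordinate is 0; set
#' `zero_rule = "pair"` to restrict it to (0, 0).
#'
#' @param records canonical occurrence tibble.
#' @param min_latitude southern study limit in decimal degrees (default 20).
#' @param zero_rule `"either"` (default) or `"pair"`.
#' @return List with `kept`, `removed` and a per-rule `report` (a record may
#'   trip several rules; it is removed once).
#' @export
filter_coordinates <- function(records, min_latitude = 20,
                               zero_rule = c("either", "pair")) {
  zero_rule <- match.arg(zero_rule)
  lat <- records$decimalLatitude
  lon <- records$decimalLongitude
  r_missing <- is.na(lat) | is.na(lon)
  r_equal <- !r_missing & lat == lon
  r_zero <- if (zero_rule == "either") {
    !r_missing & (lat == 0 | lon == 0)
  } else {
    !r_missing & lat == 0 & lon == 0
  }
  r_integer <- !r_missing & lat == trunc(lat) & lon == trunc(lon)
  r_south <- !r_missing & lat < min_latitude
  drop <- r_missing | r_equal | r_zero | r_integer | r_south
  .filter_result(records, drop,
                 .rule_report(missing_coordinates = sum(r_missing),
                              lat_equals_lon = sum(r_equal),
                              zero_coordinate = sum(r_zero),
                              integer_coordinates = sum(r_integer),
                              below_min_latitude = sum(r_south)))
}

#' Remove records inconsistent with their declared country
#'
#' Keeps a record iff its coordinates fall inside the rectangle of its
#' `countryCode` expanded by `buffer_deg` on every side. Records with no
#' country code skip the test (missing metadata is not a mismatch); records
#' with a code absent from the country table are flagged unmatchable, kept,
#' and counted separately.
#'
#' @param records canonical occurrence tibble.
#' @param countries country-rectangle table from [read_countries()].
#' @param buffer_deg buffer in decimal degrees (default 0.1, about 10 km).
#' @return List with `kept`, `removed` and `report`.
#' @export
filter_country_mismatch <- function(records, countries, buffer_deg = 0.1) {
  idx <- match(records$countryCode, countries$countryCode)
  known <- !is.na(records$countryCode) & !is.na(idx)
  unmatchable <- !is.na(records$countryCode) & is.na(idx)
  inside <- rep(TRUE, nrow(records))
  k <- which(known & !is.na(records$decimalLatitude) &
               !is.na(records$decimalLongitude))
  if (length(k) > 0) {
    ci <- idx[k]
    inside[k] <-
      records$decimalLongitude[k] >= countries$lon_min[ci] - buffer_deg &
      records$decimalLongitude[k] <= countries$lon_max[ci] + buffer_deg &
      records$decimalLatitude[k] >= countries$lat_min[ci] - buffer_deg &
      records$decimalLatitude[k] <= countries$lat_max[ci] + buffer_deg
  }
  drop <- known & !inside
  .filter_result(records, drop,
                 .rule_report(country_mismatch = sum(drop),
                              country_unmatchable = sum(unmatchable)))
}

#' Remove records at suspect gazetteer localities
#'
#' Drops records within each gazetteer entry's radius (great-circle
#' distance) of that entry: country centroids, biodiversity institutions,
#' repository headquarters. The report itemises removals per entry kind.
#'
#' @param records canonical occurrence tibble.
#' @param gazetteer tibble from [read_gazetteer()].
#' @return List with `kept`, `removed` and `report`.
#' @export
filter_gazetteer <- function(records, gazetteer) {
  ok <- !is.na(records$decimalLatitude) & !is.na(records$decimalLongitude)
  drop <- rep(FALSE, nrow(records))
  kind_hit <- stats::setNames(integer(length(unique(gazetteer$kind))),
                              unique(gazetteer$kind))
  if (any(ok) && nrow(gazetteer) > 0) {
    pts <- cbind(records$decimalLongitude[ok], records$decimalLatitude[ok])
    hit <- matrix(FALSE, nrow(pts), nrow(gazetteer))
    for (j in seq_len(nrow(gazetteer))) {
      d <- geosphere::distHaversine(pts, c(gazetteer$lon[j], gazetteer$lat[j]))
      hit[, j] <- d <= gazetteer$radius_km[j] * 1000
    }
    drop[ok] <- rowSums(hit) > 0
    for (kd in names(kind_hit)) {
      cols <- which(gazetteer$kind == kd)
      kind_hit[kd] <- sum(rowSums(hit[, cols, drop = FALSE]) > 0)
    }
  }
  .filter_result(records, drop, .rule_report(kind_hit))
}

.species_ranks <- c("species", "subspecies", "variety", "form")

#' Keep records identified at species level or lower
#'
#' Retains ranks species, subspecies, variety and form. Records with a
#' missing rank are kept when the name parses as a binomial (or lower) and
#' removed when it is uninomial.
#'
#' @param records canonical occurrence tibble.
#' @return List with `kept`, `removed` and `report`.
#' @export
filter_rank <- function(records) {
  rk <- tolower(records$taxonRank)
  nm <- normalise_name(records$scientificName)
  uninomial <- attr(nm, "uninomial")
  keep <- ifelse(!is.na(rk) & rk != "",
                 rk %in% .species_ranks,
                 !uninomial)
  drop <- !keep
  .filter_result(records, drop,
                 .rule_report(above_species_rank = sum(drop, na.rm = TRUE)))
}

#' Assign records to grid cells, latitudinal bands and regions
#'
#' Projects each record to the equal-area plane and indexes it into the
#' half-open 100-km cells of the grid; the cell's row gives the latitudinal
#' band (1 at the southern study limit, increasing northwards) and the
#' record's longitude gives the region. Points outside the grid extent are
#' excluded and counted as out_of_grid.
#'
#' @param records canonical occurrence tibble with coordinates.
#' @param grid a [study_grid()].
#' @return List with `records` (annotated with `cell_id`, `band`, `region`),
#'   `removed` (out-of-grid rows) and `report`.
#' @export
assign_cells <- function(records, grid) {
  stopifnot(inherits(grid, "study_grid"))
  p <- ease2_project(records$decimalLongitude, records$decimalLatitude)
  ix <- floor((p$x - grid$origin[1]) / grid$cell_size_m)
  iy <- floor((p$y - grid$origin[2]) / grid$cell_size_m)
  # the global upper edge belongs to the last row
  top <- !is.na(p$y) & p$y >= grid$y_top
  iy[top] <- pmin(iy[top], grid$n_bands - 1)
  out <- is.na(iy) | is.na(ix) | iy < 0 | iy >= grid$n_bands
  ann <- records[!out, , drop = FALSE]
  ann$cell_id <- sprintf("x%03d_y%02d", ix[!out], iy[!out] + 1L)
  ann$band <- as.integer(iy[!out] + 1L)
  ann$region <- .grid_region(grid, ann$decimalLongitude)
  list(records = ann,
       removed = records[out, , drop = FALSE],
       report = .rule_report(out_of_grid = sum(out)))
}

#' Run the full geographic pre-processing chain
#'
#' Applies, in order: fossil filter, date filter, coordinate filter, country
#' mismatch (when a country table is given), gazetteer proximity (when a
#' gazetteer is given), rank filter, then cell/band/region assignment. All
#' rules are record-level predicates, so the kept set does not depend on
#' this order.
#'
#' @param records canonical occurrence tibble.
#' @param grid a [study_grid()].
#' @param countries optional country-rectangle table.
#' @param gazetteer optional gazetteer tibble.
#' @param buffer_deg country-mismatch buffer in degrees.
#' @return List with `records` (kept, cell-annotated), `removed` (all
#'   discarded rows) and a stacked per-rule `report`.
#' @export
preprocess <- function(records, grid, countries = NULL, gazetteer = NULL,
                       buffer_deg = 0.1) {
  steps <- list(
    fossil = function(x) filter_fossil(x),
    dates = function(x) filter_dates(x),
    coordinates = function(x) filter_coordinates(x, grid$min_latitude))
  if (!is.null(countries)) {
    steps$country <- function(x) filter_country_mismatch(x, countries, buffer_deg)
  }
  if (!is.null(gazetteer)) {
    steps$gazetteer <- function(x) filter_gazetteer(x, gazetteer)
  }
  steps$rank <- function(x) filter_rank(x)

  kept <- records
  removed <- list()
  reports <- list()
  for (nm in names(steps)) {
    res <- steps[[nm]](kept)
    kept <- res$kept
    removed[[nm]] <- res$removed
    reports[[nm]] <- dplyr::mutate(res$report, stage = nm, .before = 1)
  }
  cells <- assign_cells(kept, grid)
  removed$grid <- cells$removed
  reports$grid <- dplyr::mutate(cells$report, stage = "grid", .before = 1)
  list(records = cells$records,
       removed = dplyr::bind_rows(removed),
       report = dplyr::bind_rows(reports))
}
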
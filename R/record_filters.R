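# Cleaning filters applied after taxonomic annotation: the two duplicate
# criteria, the preserved-specimen filter and the five temporal windows;
# their composition into named curation scenarios; and per-cell discard
# accounting.

#' Define a duplicate key
#'
#' Duplicates are records agreeing on species name, coordinates and date of
#' collection, optionally also on the collector string. Coordinates are
#' compared by exact canonical decimal representation unless a rounding
#' precision is requested.
#'
#' @param collector include `recordedBy` in the key?
#' @param coord_digits optional number of decimal digits to round
#'   coordinates to before comparison (default: no rounding).
#' @param name_col column holding the species name to compare (default the
#'   scenario's standardised name).
#' @return A `duplicate_key` object.
#' @export
duplicate_key <- function(collector = FALSE, coord_digits = NULL,
                          name_col = "acceptedName") {
  structure(list(collector = collector, coord_digits = coord_digits,
                 name_col = name_col),
            class = "duplicate_key")
}

.canon_num <- function(x, digits = NULL) {
  if (!is.null(digits)) x <- round(x, digits)
  sprintf("%.12g", x)
}

#' Remove duplicate records
#'
#' Within each group of records sharing every key component, exactly one
#' record (the first in input order) is kept. A record missing any key
#' component can never be positively identified as a duplicate, so it forms
#' a singleton group and is always kept.
#'
#' @param records annotated occurrence tibble.
#' @param key a [duplicate_key()].
#' @return List with `kept`, `removed` and `report`; the report also gives
#'   the number of multi-record duplicate groups.
#' @export
dedupe <- function(records, key = duplicate_key()) {
  stopifnot(inherits(key, "duplicate_key"))
  nm <- records[[key$name_col]]
  parts <- list(nm,
                .canon_num(records$decimalLatitude, key$coord_digits),
                .canon_num(records$decimalLongitude, key$coord_digits),
                records$eventDate)
  missing_part <- is.na(nm) | is.na(records$decimalLatitude) |
    is.na(records$decimalLongitude) | is.na(records$eventDate)
  if (key$collector) {
    parts <- c(parts, list(records$recordedBy))
    missing_part <- missing_part | is.na(records$recordedBy)
  }
  gk <- do.call(paste, c(parts, sep = "\r"))
  gk[missing_part] <- paste0("\r_singleton_", which(missing_part))
  drop <- duplicated(gk)
  n_groups_multi <- sum(table(gk) > 1)
  .filter_result(records, drop,
                 .rule_report(duplicate = sum(drop),
                              duplicate_groups = n_groups_multi))
}

#' Filter by basis of record
#'
#' Keeps records whose `basisOfRecord` is in the allowed set; matching is
#' case- and format-insensitive, so `"PreservedSpecimen"` and
#' `"PRESERVED_SPECIMEN"` are the same value.
#'
#' @param records occurrence tibble.
#' @param allowed character vector of allowed basis values.
#' @return List with `kept`, `removed` and `report`.
#' @export
filter_basis <- function(records, allowed) {
  keep <- .norm_basis(records$basisOfRecord) %in% .norm_basis(allowed)
  .filter_result(records, !keep,
                 .rule_report(basis_of_record = sum(!keep)))
}

#' Filter by collection year
#'
#' When `require_year` is set, records without a year are removed;
#' otherwise a record is removed only when its year is present and outside
#' `[min_year, max_year]`. All the standard temporal windows (with year
#' since 1600; since 1900; since 1970; 1970-2000; since 1990) are
#' expressible.
#'
#' @param records occurrence tibble.
#' @param min_year,max_year inclusive year window.
#' @param require_year remove records lacking a year?
#' @return List with `kept`, `removed` and `report`.
#' @export
filter_temporal <- function(records, min_year = -Inf, max_year = Inf,
                            require_year = FALSE) {
  if (min_year > max_year) {
    stop("min_year must not exceed max_year", call. = FALSE)
  }
  yr <- records$year
  out_window <- !is.na(yr) & (yr < min_year | yr > max_year)
  no_year <- is.na(yr) & require_year
  .filter_result(records, out_window | no_year,
                 .rule_report(outside_window = sum(out_window),
                              missing_year = sum(no_year)))
}

#' The standard set of cleaning filters
#'
#' The eight filters examined one at a time when mapping well-sampled
#' cells: two duplicate criteria, the preserved-specimen restriction, and
#' five temporal windows.
#'
#' @return Named list of filter definitions; apply one with
#'   [apply_cleaning_filter()].
#' @export
cleaning_filters <- function() {
  list(
    dup_collector = list(kind = "dedupe", key = duplicate_key(collector = TRUE)),
    dup_date = list(kind = "dedupe", key = duplicate_key(collector = FALSE)),
    specimen = list(kind = "basis", allowed = "PreservedSpecimen"),
    year1600_req = list(kind = "temporal", min_year = 1600, require_year = TRUE),
    year1900 = list(kind = "temporal", min_year = 1900, require_year = FALSE),
    year1970 = list(kind = "temporal", min_year = 1970, require_year = FALSE),
    year1970_2000 = list(kind = "temporal", min_year = 1970, max_year = 2000,
                         require_year = FALSE),
    year1990 = list(kind = "temporal", min_year = 1990, require_year = FALSE)
  )
}

#' Apply one named cleaning filter
#'
#' @param records annotated occurrence tibble.
#' @param filter one element of [cleaning_filters()], or its name.
#' @return List with `kept`, `removed` and `report`.
#' @export
apply_cleaning_filter <- function(records, filter) {
  if (is.character(filter)) {
    filter <- cleaning_filters()[[filter]]
    if (is.null(filter)) stop("unknown cleaning filter", call. = FALSE)
  }
  switch(filter$kind,
    dedupe = dedupe(records, filter$key),
    basis = filter_basis(records, filter$allowed),
    temporal = filter_temporal(records,
                               min_year = filter$min_year %||% -Inf,
                               max_year = filter$max_year %||% Inf,
                               require_year = isTRUE(filter$require_year)),
    stop("unknown filter kind: ", filter$kind, call. = FALSE))
}

#' Define a curation scenario
#'
#' A scenario names a taxonomy source, optional basis and temporal filters,
#' and a duplicate key; applied in that order (deduplication last).
#'
#' @param name unique scenario name.
#' @param taxonomy_source `"consensus"` or the label of a single
#'   standardisation source whose `accepted_<label>` annotation exists on
#'   the records.
#' @param basis_allowed optional allowed `basisOfRecord` set.
#' @param temporal optional list with `min_year`, `max_year`,
#'   `require_year`.
#' @param key a [duplicate_key()].
#' @return A `curation_scenario` object.
#' @export
curation_scenario <- function(name, taxonomy_source = "consensus",
                              basis_allowed = NULL, temporal = NULL,
                              key = duplicate_key()) {
  structure(list(name = name, taxonomy_source = taxonomy_source,
                 basis_allowed = basis_allowed, temporal = temporal,
                 key = key),
            class = "curation_scenario")
}

#' The four standard curation scenarios
#'
#' date-TNRS, date-cons, date-specim and date-1970: each removes duplicates
#' on species name + coordinates + date of collection, under different
#' taxonomy sources and record subsets.
#'
#' @param tnrs_label label of the TNRS-like standardisation source present
#'   on the annotated records (default `"TNRS"`).
#' @return Named list of [curation_scenario()] objects.
#' @export
default_scenarios <- function(tnrs_label = "TNRS") {
  list(
    `date-TNRS` = curation_scenario("date-TNRS", taxonomy_source = tnrs_label),
    `date-cons` = curation_scenario("date-cons", taxonomy_source = "consensus"),
    `date-specim` = curation_scenario("date-specim",
                                      taxonomy_source = "consensus",
                                      basis_allowed = "PreservedSpecimen"),
    `date-1970` = curation_scenario("date-1970", taxonomy_source = "consensus",
                                    temporal = list(min_year = 1970))
  )
}

#' Apply a curation scenario
#'
#' Stage order: taxonomy selection, basis filter, temporal filter, then
#' deduplication (last, so duplicate detection sees only the records that
#' survive extraction). The records must carry the taxonomy annotations:
#' `acceptedName` for the consensus and `accepted_<label>` columns for the
#' individual sources.
#'
#' @param records annotated occurrence tibble.
#' @param scenario a [curation_scenario()].
#' @return List with `records` (curated), `removed`, a per-stage `report`
#'   (`n_in = n_removed + n_out` at every stage) and a per-rule
#'   `rule_report`.
#' @export
apply_scenario <- function(records, scenario) {
  stopifnot(inherits(scenario, "curation_scenario"))
  tax_col <- if (scenario$taxonomy_source == "consensus") "acceptedName"
             else paste0("accepted_", scenario$taxonomy_source)
  if (!tax_col %in% names(records)) {
    stop("unknown taxonomy source for scenario '", scenario$name, "': ",
         scenario$taxonomy_source, call. = FALSE)
  }
  work <- records
  work$species_scenario <- work[[tax_col]]
  reports <- list()
  rules <- list()
  removed <- list()
  step <- function(res, nm) {
    removed[[nm]] <<- res$removed
    n_in <- nrow(res$kept) + nrow(res$removed)
    reports[[nm]] <<- tibble::tibble(stage = nm, n_in = n_in,
                                     n_removed = nrow(res$removed),
                                     n_out = nrow(res$kept))
    rules[[nm]] <<- dplyr::mutate(res$report, stage = nm, .before = 1)
    res$kept
  }
  work <- step(.filter_result(work, is.na(work$species_scenario),
                              .rule_report(unresolved_name =
                                             sum(is.na(work$species_scenario)))),
               "taxonomy")
  if (!is.null(scenario$basis_allowed)) {
    work <- step(filter_basis(work, scenario$basis_allowed), "basis")
  }
  if (!is.null(scenario$temporal)) {
    tp <- scenario$temporal
    work <- step(filter_temporal(work,
                                 min_year = tp$min_year %||% -Inf,
                                 max_year = tp$max_year %||% Inf,
                                 require_year = isTRUE(tp$require_year)),
                 "temporal")
  }
  key <- scenario$key
  key$name_col <- "species_scenario"
  work <- step(dedupe(work, key), "dedupe")
  list(records = work,
       removed = dplyr::bind_rows(removed),
       report = dplyr::bind_rows(reports),
       rule_report = dplyr::bind_rows(rules))
}

#' Per-cell discard proportions between two datasets
#'
#' For each cell of `before`, the proportion of records and of observed
#' species lost in `after`: `1 - n_after/n_before` and
#' `1 - S_after/S_before`. Cells absent from `after` report 1; cells absent
#' from `before` are undefined and omitted with a warning.
#'
#' @param before,after cell-annotated occurrence tibbles; species are read
#'   from `species_col`.
#' @param species_col name column used for richness (default
#'   `acceptedName`).
#' @return Tibble with `cell_id`, `prop_records_discarded`,
#'   `prop_species_discarded`.
#' @export
discard_proportions <- function(before, after, species_col = "acceptedName") {
  summ <- function(x) {
    dplyr::summarise(dplyr::group_by(x, .data$cell_id),
                     n = dplyr::n(),
                     s = dplyr::n_distinct(.data[[species_col]]),
                     .groups = "drop")
  }
  b <- summ(before)
  a <- summ(after)
  orphan <- setdiff(a$cell_id, b$cell_id)
  if (length(orphan) > 0) {
    warning("cells present only in `after` omitted: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(b, a, by = "cell_id", suffix = c("_before", "_after")) |>
    dplyr::mutate(
      n_after = dplyr::coalesce(.data$n_after, 0L),
      s_after = dplyr::coalesce(.data$s_after, 0L),
      prop_records_discarded = 1 - .data$n_after / .data$n_before,
      prop_species_discarded = 1 - .data$s_after / .data$s_before) |>
    dplyr::select("cell_id", "prop_records_discarded",
                  "prop_species_discarded")
}
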
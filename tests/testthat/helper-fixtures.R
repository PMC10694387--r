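# Small in-code fixtures shared across the suite.

# canonical record tibble with clean in-grid defaults; override any field
make_records <- function(n = 1, ...) {
  out <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    scientificName = "Bryum argenteum",
    decimalLatitude = 48.123456,
    decimalLongitude = 2.456789,
    countryCode = NA_character_,
    eventDate = "1985-06-15",
    year = 1985L,
    basisOfRecord = "PreservedSpecimen",
    recordedBy = "Collector_001",
    datasetName = "GBIF",
    taxonRank = "species")
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# exhaustive-enumeration rarefaction oracle: mean richness over all
# C(N, m) record subsets (feasible for small N only)
rarefy_enum <- function(counts, m) {
  ids <- rep(seq_along(counts), counts)
  if (m == 0) return(0)
  if (m == length(ids)) return(length(unique(ids)))
  combs <- utils::combn(length(ids), m)
  mean(apply(combs, 2, function(i) length(unique(ids[i]))))
}

# two-segment tent profile used for breakpoint truth
tent_profile <- function(x, bp, b0, s1, s2) {
  b0 + s1 * (pmin(x, bp) - 1) + s2 * pmax(x - bp, 0)
}

# a taxon lookup from a compact row list: list(c(raw, accepted, status), ...)
tiny_lookup <- function(rows, label = "src", ...) {
  taxon_lookup(tibble::tibble(
    raw_name = vapply(rows, function(r) r[[1]], ""),
    accepted_name = vapply(rows, function(r)
      if (is.na(r[[2]]) || r[[2]] == "") NA_character_ else r[[2]], ""),
    status = vapply(rows, function(r) r[[3]], "")),
    source_label = label, ...)
}

# a standardisation map (as produced by standardise()) straight from rows:
# list(c(raw, accepted_or_NA), ...)
tiny_map <- function(rows) {
  raw <- vapply(rows, function(r) r[[1]], "")
  acc <- vapply(rows, function(r)
    if (is.na(r[[2]])) NA_character_ else r[[2]], "")
  tibble::tibble(raw_name = raw,
                 raw_norm = as.character(normalise_name(raw)),
                 accepted_name = acc,
                 status = ifelse(is.na(acc), "unresolved", "accepted"))
}

# error-free single-region generator config for targeted tests
clean_config <- function(seed = 1, n_records = 2000, ...) {
  args <- list(
    seed = seed, regions = "EuropeNAfrica", n_records = n_records,
    breakpoint_band = 40, slope_below = 2, slope_above = -2,
    region_weights = 1,
    p_zero_coord = 0, p_integer_coord = 0, p_lat_eq_lon = 0,
    p_country_mismatch = 0, p_centroid = 0, p_missing_date = 0,
    p_invalid_date = 0, p_fossil = 0, duplicate_rate = 0)
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(synthetic_config, args)
}
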
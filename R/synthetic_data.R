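# Synthetic occurrence datasets with known planted structure: a piecewise-
# linear latitudinal richness gradient per region, spatially clustered
# sampling effort, planted coordinate/temporal/basis errors, duplicate
# groups, name variants across standardisation sources, and a ground-truth
# ledger so every downstream stage can be checked exactly.

.synth_genera <- c("Bryum", "Sphagnum", "Hypnum", "Dicranum", "Polytrichum",
                   "Grimmia", "Tortula", "Orthotrichum", "Mnium",
                   "Fontinalis", "Racomitrium", "Pohlia")
.synth_syllables <- c("ar", "ber", "cau", "den", "el", "fol", "gra", "hir",
                      "lan", "mon", "nit", "ov", "pal", "rub", "ser", "tor",
                      "vel", "umb", "lut", "cal")
.synth_suffixes <- c("um", "ens", "oid")
# synonym binomials draw their genus from a list disjoint from the accepted
# genera, so a synonym can never collide with an accepted name
.synth_syn_genera <- c("Webera", "Leskea", "Neckera", "Fissidens", "Bartramia",
                       "Splachnum", "Leucobryum", "Climacium", "Thuidium",
                       "Plagiomnium", "Aulacomnium", "Schistidium")

#' Configuration for the synthetic occurrence generator
#'
#' Defaults emulate the documented structure of public moss occurrence
#' data in the temperate Northern Hemisphere: about 4% of records undated;
#' a 0.26 per-record duplication probability with 15% of copies carrying a
#' different collector string, so a date-based duplicate key removes about
#' 20% of the emitted dataset and a collector-inclusive key about 17%;
#' clustered log-normal sampling effort; a mixed basis of record; and
#' per-region richness peaks at bands 30 (North America), 40 (Europe/N.
#' Africa) and 18 (Asia).
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param regions regions to populate (subset of the grid's labels).
#' @param n_bands number of latitudinal bands.
#' @param base_richness true richness at band 1.
#' @param breakpoint_band band of peak richness; scalar or named per
#'   region, each in `[2, n_bands - 1]`.
#' @param slope_below,slope_above species gained per band below / above the
#'   breakpoint; scalar or named per region. True richness must stay
#'   positive on every band.
#' @param n_records number of base records (before duplication).
#' @param region_weights share of records per region.
#' @param cells_per_band sampled cells per band per region.
#' @param effort_sd log-normal sd of effort across active cells.
#' @param p_zero_coord,p_integer_coord,p_lat_eq_lon,p_country_mismatch,p_centroid,p_missing_date,p_invalid_date,p_fossil
#'   per-record planting probabilities of each error class (independent; a
#'   record may carry several).
#' @param duplicate_rate probability a base record gets a duplicate copy.
#' @param p_duplicate_new_collector probability the copy names a different
#'   collector.
#' @param basis_mix named probability vector over `basisOfRecord` values.
#' @param year_range inclusive collection-year range.
#' @param n_species_per_region optional cap on the species pool; the
#'   gradient profile must fit within it.
#' @param synonym_tables list of name-variation and lookup-source rates:
#'   `source_labels`, `coverage` (probability a source resolves a species),
#'   `p_variant_detect`, `p_divergence`, `p_synonym_record`,
#'   `p_variant_record`, `p_authorship_record`, `p_infraspecific_record`.
#' @param gazetteer_radius_km radius of gazetteer entries.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             regions = c("NorthAmerica", "EuropeNAfrica", "Asia"),
                             n_bands = 49,
                             base_richness = 10,
                             breakpoint_band = c(NorthAmerica = 30,
                                                 EuropeNAfrica = 40,
                                                 Asia = 18),
                             slope_below = 2,
                             slope_above = c(NorthAmerica = -2,
                                             EuropeNAfrica = -2,
                                             Asia = -1),
                             n_records = 20000,
                             region_weights = c(NorthAmerica = 0.25,
                                                EuropeNAfrica = 0.7,
                                                Asia = 0.05),
                             cells_per_band = 2,
                             effort_sd = 0.5,
                             p_zero_coord = 0.01,
                             p_integer_coord = 0.01,
                             p_lat_eq_lon = 0.01,
                             p_country_mismatch = 0.01,
                             p_centroid = 0.01,
                             p_missing_date = 0.04,
                             p_invalid_date = 0.005,
                             p_fossil = 0.01,
                             duplicate_rate = 0.26,
                             p_duplicate_new_collector = 0.15,
                             basis_mix = c(PreservedSpecimen = 0.5,
                                           HumanObservation = 0.45,
                                           MaterialSample = 0.05),
                             year_range = c(1900, 2020),
                             n_species_per_region = NULL,
                             synonym_tables = list(),
                             gazetteer_radius_km = 1) {
  pick <- function(x, rg) {
    if (is.null(names(x))) rep(unname(x), length(rg)) else unname(x[rg])
  }
  st_default <- list(source_labels = c("GBIF", "TPL", "TNRS", "Tropicos", "WFO"),
                     coverage = 0.9, p_variant_detect = 0.8,
                     p_divergence = 0.03, p_synonym_record = 0.15,
                     p_variant_record = 0.05, p_authorship_record = 0.25,
                     p_infraspecific_record = 0.05)
  synonym_tables <- utils::modifyList(st_default, synonym_tables)
  cfg <- list(seed = as.integer(seed), regions = regions, n_bands = n_bands,
              base_richness = base_richness,
              breakpoint_band = stats::setNames(pick(breakpoint_band, regions), regions),
              slope_below = stats::setNames(pick(slope_below, regions), regions),
              slope_above = stats::setNames(pick(slope_above, regions), regions),
              n_records = n_records,
              region_weights = stats::setNames(pick(region_weights, regions), regions),
              cells_per_band = cells_per_band, effort_sd = effort_sd,
              p_zero_coord = p_zero_coord, p_integer_coord = p_integer_coord,
              p_lat_eq_lon = p_lat_eq_lon,
              p_country_mismatch = p_country_mismatch,
              p_centroid = p_centroid, p_missing_date = p_missing_date,
              p_invalid_date = p_invalid_date, p_fossil = p_fossil,
              duplicate_rate = duplicate_rate,
              p_duplicate_new_collector = p_duplicate_new_collector,
              basis_mix = basis_mix, year_range = year_range,
              n_species_per_region = n_species_per_region,
              synonym_tables = synonym_tables,
              gazetteer_radius_km = gazetteer_radius_km)
  probs <- c(p_zero_coord, p_integer_coord, p_lat_eq_lon, p_country_mismatch,
             p_centroid, p_missing_date, p_invalid_date, p_fossil,
             duplicate_rate, p_duplicate_new_collector)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_records <= 0) stop("n_records must be positive", call. = FALSE)
  if (any(cfg$breakpoint_band < 2 | cfg$breakpoint_band > n_bands - 1)) {
    stop("breakpoint_band must lie in [2, n_bands - 1]", call. = FALSE)
  }
  for (rg in regions) {
    r <- .synth_profile(cfg, rg)
    if (any(r <= 0)) {
      stop("degenerate slopes: true richness non-positive in region ", rg,
           call. = FALSE)
    }
  }
  structure(cfg, class = "synthetic_config")
}

# true per-band richness profile of one region; richness is a species
# count, so fractional slopes give a rounded staircase profile
.synth_profile <- function(config, region) {
  b <- seq_len(config$n_bands)
  bp <- config$breakpoint_band[region]
  s1 <- config$slope_below[region]
  s2 <- config$slope_above[region]
  round(config$base_richness + s1 * (pmin(b, bp) - 1) + s2 * pmax(b - bp, 0))
}

# deterministic pool of unique binomials (needs RNG state set by caller)
.synth_species_names <- function(n) {
  combos <- expand.grid(g = .synth_genera, s1 = .synth_syllables,
                        s2 = .synth_syllables, sf = .synth_suffixes,
                        stringsAsFactors = FALSE)
  stopifnot(n <= nrow(combos))
  idx <- sample.int(nrow(combos), n)
  paste(combos$g[idx], paste0(combos$s1[idx], combos$s2[idx], combos$sf[idx]))
}

#' Generate the true species community and its richness gradient
#'
#' Per region, builds a species pool whose per-band richness follows the
#' configured two-segment piecewise-linear profile exactly: species are
#' activated as richness rises towards the breakpoint and retired
#' (first-in, first-out) as it falls, giving each species a contiguous band
#' range. Deterministic given the seed.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_community`: per-region species tables (species,
#'   band_min, band_max, synonym and orthographic-variant strings) and the
#'   true richness tibble (region, band, richness_true).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  need <- vapply(config$regions, function(rg) {
    r <- .synth_profile(config, rg)
    r[1] + sum(pmax(diff(r), 0))
  }, numeric(1))
  if (!is.null(config$n_species_per_region) &&
      any(need > config$n_species_per_region)) {
    stop("n_species_per_region too small for the richness profile",
         call. = FALSE)
  }
  pool <- .synth_species_names(sum(need))
  offsets <- c(0, cumsum(need))
  regions <- list()
  rich <- list()
  for (i in seq_along(config$regions)) {
    rg <- config$regions[i]
    r <- .synth_profile(config, rg)
    names_rg <- pool[(offsets[i] + 1):offsets[i + 1]]
    active <- integer(0)  # indices into names_rg, FIFO
    band_min <- integer(length(names_rg))
    band_max <- integer(length(names_rg))
    nxt <- 1L
    for (b in seq_len(config$n_bands)) {
      delta <- if (b == 1) r[1] else r[b] - r[b - 1]
      if (delta > 0) {
        new_idx <- nxt:(nxt + delta - 1)
        band_min[new_idx] <- b
        active <- c(active, new_idx)
        nxt <- nxt + delta
      } else if (delta < 0) {
        out <- active[seq_len(-delta)]
        band_max[out] <- b - 1L
        active <- active[-seq_len(-delta)]
      }
    }
    band_max[active] <- config$n_bands
    sp <- tibble::tibble(species = names_rg, band_min = band_min,
                         band_max = band_max)
    # one synonym (disjoint genus, same epithet) and one orthographic
    # variant (epithet ending no accepted name can carry)
    ep <- sub("^\\S+ ", "", sp$species)
    gen <- sub(" .*$", "", sp$species)
    sp$synonym <- paste(.synth_syn_genera[match(gen, .synth_genera)], ep)
    sp$variant <- paste(gen, paste0(ep, "ii"))
    regions[[rg]] <- sp
    rich[[rg]] <- tibble::tibble(region = rg, band = seq_len(config$n_bands),
                                 richness_true = r)
  }
  structure(list(regions = regions,
                 richness = dplyr::bind_rows(rich),
                 config = config),
            class = "synthetic_community")
}

# synthetic rectangle countries covering each grid region, 3 slices each
.synth_countries <- function(grid) {
  bounds <- c(-180, grid$region_breaks, 180)
  out <- list()
  for (i in seq_along(grid$region_labels)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    cuts <- seq(lo, hi, length.out = 4)
    out[[i]] <- tibble::tibble(
      countryCode = paste0(substr(grid$region_labels[i], 1, 1), 1:3),
      lon_min = cuts[1:3], lon_max = cuts[2:4],
      lat_min = 20, lat_max = 90,
      region = grid$region_labels[i])
  }
  x <- dplyr::bind_rows(out)
  # population-style centroids, off the geometric centre and never on
  # integer coordinates
  x$centroid_lon <- (x$lon_min + x$lon_max) / 2 + 0.37
  x$centroid_lat <- x$lat_min + 0.57 * (x$lat_max - x$lat_min) + 0.13
  x
}

.synth_gazetteer <- function(countries, radius_km) {
  g1 <- tibble::tibble(label = paste0("centroid_", countries$countryCode),
                       lat = countries$centroid_lat,
                       lon = countries$centroid_lon,
                       radius_km = radius_km,
                       kind = "country_centroid")
  mid <- countries[seq(2, nrow(countries), by = 3), ]
  g2 <- tibble::tibble(label = paste0("institution_", mid$countryCode),
                       lat = mid$centroid_lat + 3.137,
                       lon = mid$centroid_lon + 5.921,
                       radius_km = radius_km,
                       kind = "institution")
  dplyr::bind_rows(g1, g2)
}

#' Generate synthetic occurrence records with a ground-truth ledger
#'
#' Draws base records with spatially clustered effort (log-normal weights
#' over the active cells of each region), plants each error class
#' independently per record, then appends duplicate copies. All planted
#' structure, the true species, cell, band, country and duplicate group of
#' every record, is returned in the ledger. Clean coordinates are
#' continuous draws, so no unplanted record can trip a coordinate rule, and
#' clean points are kept away from gazetteer localities.
#'
#' @param community a [generate_community()] result.
#' @param config the same [synthetic_config()].
#' @param grid the [study_grid()] to generate into (defaults to the
#'   standard grid with the config's band count).
#' @param cells optional active-cell table (`region`, `band`, `ix`, `w`)
#'   from a previous call's `$cells`, so two strata (e.g. specimens and
#'   observations with different gradients) can share the same cells.
#' @return List with `records` (canonical occurrence tibble), `truth`
#'   (ledger tibble, one row per record), `cells` (active-cell table),
#'   `countries`, `gazetteer`.
#' @export
generate_records <- function(community, config, grid = NULL, cells = NULL) {
  stopifnot(inherits(community, "synthetic_community"),
            inherits(config, "synthetic_config"))
  if (is.null(grid)) grid <- study_grid(n_bands = config$n_bands)
  set.seed(config$seed + 1L)
  countries <- .synth_countries(grid)
  gaz <- .synth_gazetteer(countries, config$gazetteer_radius_km)
  bounds <- c(-180, grid$region_breaks, 180)

  if (is.null(cells)) {
    per_cells <- list()
    for (rg in config$regions) {
      ri <- match(rg, grid$region_labels)
      # columns fully inside the region, with a half-degree margin
      xr <- ease2_project(c(bounds[ri] + 0.5, bounds[ri + 1] - 0.5), c(45, 45))$x
      ix_lo <- ceiling((xr[1] - grid$origin[1]) / grid$cell_size_m)
      ix_hi <- floor((xr[2] - grid$origin[1]) / grid$cell_size_m) - 1L
      cc <- tibble::tibble(
        region = rg,
        band = rep(seq_len(config$n_bands), each = config$cells_per_band),
        ix = as.vector(vapply(seq_len(config$n_bands), function(b)
          sample(ix_lo:ix_hi, config$cells_per_band),
          integer(config$cells_per_band))))
      cc$w <- stats::rlnorm(nrow(cc), 0, config$effort_sd)
      per_cells[[rg]] <- cc
    }
    cells <- dplyr::bind_rows(per_cells)
  }
  per_region <- list()
  for (rg in config$regions) {
    n_rg <- round(config$n_records * config$region_weights[rg] /
                    sum(config$region_weights))
    if (n_rg == 0) next
    cc <- cells[cells$region == rg, , drop = FALSE]
    pick <- sample.int(nrow(cc), n_rg, replace = TRUE, prob = cc$w)
    df <- cc[pick, c("band", "ix")]
    df$region <- rg
    per_region[[rg]] <- df
  }
  base <- dplyr::bind_rows(per_region)
  n <- nrow(base)

  # uniform point inside each record's cell, inverse-projected; resampled
  # while within twice the gazetteer radius of any suspect locality
  draw_points <- function(idx) {
    yr <- .band_y_range(grid, base$band[idx])
    x <- grid$origin[1] + (base$ix[idx] + stats::runif(length(idx))) * grid$cell_size_m
    y <- yr[, 1] + stats::runif(length(idx)) * (yr[, 2] - yr[, 1])
    ease2_inverse(x, y)
  }
  pts <- draw_points(seq_len(n))
  base$lon <- pts$lon
  base$lat <- pts$lat
  for (iter in 1:25) {
    near <- rep(FALSE, n)
    for (j in seq_len(nrow(gaz))) {
      d <- geosphere::distHaversine(cbind(base$lon, base$lat),
                                    c(gaz$lon[j], gaz$lat[j]))
      near <- near | d <= 2 * gaz$radius_km[j] * 1000
    }
    if (!any(near)) break
    repl <- draw_points(which(near))
    base$lon[near] <- repl$lon
    base$lat[near] <- repl$lat
  }

  # species: uniform among the species whose band range covers the cell
  base$species <- NA_character_
  for (rg in unique(base$region)) {
    sp <- community$regions[[rg]]
    in_rg <- which(base$region == rg)
    for (b in unique(base$band[in_rg])) {
      avail <- sp$species[sp$band_min <= b & sp$band_max >= b]
      sel <- in_rg[base$band[in_rg] == b]
      base$species[sel] <- avail[sample.int(length(avail), length(sel),
                                            replace = TRUE)]
    }
  }

  yr <- sample(config$year_range[1]:config$year_range[2], n, replace = TRUE)
  mo <- sample(1:12, n, replace = TRUE)
  dy <- sample(1:28, n, replace = TRUE)
  base$eventDate <- sprintf("%04d-%02d-%02d", yr, mo, dy)
  base$year <- yr
  base$recordedBy <- sprintf("Collector_%03d", sample(1:150, n, replace = TRUE))
  base$basisOfRecord <- sample(names(config$basis_mix), n, replace = TRUE,
                               prob = config$basis_mix)
  base$datasetName <- sample(c("GBIF", "CNABH", "iDigBio", "BIEN"), n,
                             replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1))
  # country containing the record's longitude (slices are globally sorted)
  base$countryCode <- countries$countryCode[
    findInterval(base$lon, countries$lon_min, rightmost.closed = TRUE)]

  # raw name forms
  st <- config$synonym_tables
  spidx <- match(base$species, unlist(lapply(community$regions, `[[`, "species")))
  all_sp <- dplyr::bind_rows(community$regions)
  u <- stats::runif(n)
  base$name_form <- ifelse(u < st$p_synonym_record, "synonym",
                    ifelse(u < st$p_synonym_record + st$p_variant_record,
                           "variant", "accepted"))
  base$scientificName <- dplyr::case_when(
    base$name_form == "synonym" ~ all_sp$synonym[spidx],
    base$name_form == "variant" ~ all_sp$variant[spidx],
    TRUE ~ base$species)
  base$taxonRank <- "species"
  infra <- stats::runif(n) < st$p_infraspecific_record
  base$scientificName[infra] <- paste(base$scientificName[infra], "var.",
                                      sub("^\\S+ ", "", base$species[infra]))
  base$taxonRank[infra] <- "variety"
  auth <- stats::runif(n) < st$p_authorship_record
  base$scientificName[auth] <- paste(base$scientificName[auth],
                                     sample(c("Hedw.", "Brid.", "Schimp.",
                                              "(L.) Sm.", "Müll.Hal."),
                                            sum(auth), replace = TRUE))

  # planted errors, independent per record; coordinate overrides are applied
  # centroid -> integer -> lat=lon -> zero so a zero-labelled record is
  # always exactly (0, 0)
  plant <- function(p) stats::runif(n) < p
  err_centroid <- plant(config$p_centroid)
  err_integer <- plant(config$p_integer_coord)
  err_lat_eq_lon <- plant(config$p_lat_eq_lon)
  err_zero <- plant(config$p_zero_coord)
  err_country <- plant(config$p_country_mismatch)
  err_missing_date <- plant(config$p_missing_date)
  err_invalid_date <- plant(config$p_invalid_date) & !err_missing_date
  err_fossil <- plant(config$p_fossil)

  own <- match(base$countryCode, countries$countryCode)
  base$lon[err_centroid] <- countries$centroid_lon[own][err_centroid]
  base$lat[err_centroid] <- countries$centroid_lat[own][err_centroid]
  base$lon[err_integer] <- round(base$lon[err_integer])
  base$lat[err_integer] <- round(base$lat[err_integer])
  base$lon[err_lat_eq_lon] <- base$lat[err_lat_eq_lon]
  base$lon[err_zero] <- 0
  base$lat[err_zero] <- 0
  # mismatched code: the middle country of another region (always far away)
  n_region <- length(grid$region_labels)
  own_region_i <- match(base$region, grid$region_labels)
  remote_i <- (own_region_i %% n_region) + 1
  base$countryCode[err_country] <-
    paste0(substr(grid$region_labels[remote_i[err_country]], 1, 1), "2")
  base$eventDate[err_missing_date] <- NA_character_
  base$year[err_missing_date] <- NA_integer_
  base$eventDate[err_invalid_date] <- sprintf("%04d-13-%02d",
                                              yr[err_invalid_date],
                                              dy[err_invalid_date])
  base$basisOfRecord[err_fossil] <- "FossilSpecimen"

  base$record_id <- sprintf("occ%07d", seq_len(n))
  base$duplicate_group <- base$record_id
  base$is_duplicate_copy <- FALSE
  base$err_zero_coord <- err_zero
  base$err_integer_coord <- err_integer
  base$err_lat_eq_lon <- err_lat_eq_lon
  base$err_country_mismatch <- err_country
  base$err_centroid <- err_centroid
  base$err_missing_date <- err_missing_date
  base$err_invalid_date <- err_invalid_date
  base$err_fossil <- err_fossil

  dup <- plant(config$duplicate_rate)
  copies <- base[dup, , drop = FALSE]
  if (nrow(copies) > 0) {
    new_coll <- stats::runif(nrow(copies)) < config$p_duplicate_new_collector
    alt <- sprintf("Collector_%03d",
                   (as.integer(sub("Collector_", "", copies$recordedBy)) + 7) %% 150 + 1)
    copies$recordedBy[new_coll] <- alt[new_coll]
    copies$record_id <- sprintf("occ%07d", n + seq_len(nrow(copies)))
    copies$is_duplicate_copy <- TRUE
    base <- dplyr::bind_rows(base, copies)
  }

  recs <- tibble::tibble(
    record_id = base$record_id,
    scientificName = base$scientificName,
    decimalLatitude = base$lat,
    decimalLongitude = base$lon,
    countryCode = base$countryCode,
    eventDate = base$eventDate,
    year = base$year,
    basisOfRecord = base$basisOfRecord,
    recordedBy = base$recordedBy,
    datasetName = base$datasetName,
    taxonRank = base$taxonRank)
  truth <- tibble::tibble(
    record_id = base$record_id,
    species_true = base$species,
    name_form = base$name_form,
    region = base$region,
    band_true = base$band,
    cell_id_true = sprintf("x%03d_y%02d", base$ix, base$band),
    duplicate_group = base$duplicate_group,
    is_duplicate_copy = base$is_duplicate_copy,
    err_zero_coord = base$err_zero_coord,
    err_integer_coord = base$err_integer_coord,
    err_lat_eq_lon = base$err_lat_eq_lon,
    err_country_mismatch = base$err_country_mismatch,
    err_centroid = base$err_centroid,
    err_missing_date = base$err_missing_date,
    err_invalid_date = base$err_invalid_date,
    err_fossil = base$err_fossil)
  list(records = recs, truth = truth, cells = cells, countries = countries,
       gazetteer = gaz)
}

#' Generate the per-source taxonomic lookup tables
#'
#' Each standardisation source resolves a species with probability
#' `coverage` (otherwise its name is listed unresolved), detects the
#' orthographic variant with probability `p_variant_detect`, and with
#' probability `p_divergence` diverges by treating the species' synonym as
#' the accepted name. Deterministic given the config seed.
#'
#' @param community a [generate_community()] result.
#' @param config the matching [synthetic_config()].
#' @return Named list of [taxon_lookup()] objects, one per source label.
#' @export
generate_lookups <- function(community, config) {
  st <- config$synonym_tables
  all_sp <- dplyr::bind_rows(community$regions)
  set.seed(config$seed + 2L)
  out <- list()
  for (src in st$source_labels) {
    covered <- stats::runif(nrow(all_sp)) < st$coverage
    diverge <- covered & (stats::runif(nrow(all_sp)) < st$p_divergence)
    has_var <- covered & (stats::runif(nrow(all_sp)) < st$p_variant_detect)
    target <- ifelse(diverge, all_sp$synonym, all_sp$species)
    rows <- list(
      tibble::tibble(raw_name = all_sp$species[covered],
                     accepted_name = target[covered],
                     status = ifelse(diverge[covered], "synonym", "accepted")),
      tibble::tibble(raw_name = all_sp$synonym[covered],
                     accepted_name = target[covered],
                     status = ifelse(diverge[covered], "accepted", "synonym")),
      tibble::tibble(raw_name = all_sp$variant[has_var],
                     accepted_name = target[has_var],
                     status = "synonym"),
      tibble::tibble(raw_name = all_sp$species[!covered],
                     accepted_name = NA_character_,
                     status = "unresolved"))
    out[[src]] <- taxon_lookup(dplyr::bind_rows(rows), source_label = src)
  }
  out
}

#' Generate a complete synthetic dataset
#'
#' Community, records with ground truth, per-source lookup tables, country
#' rectangles and gazetteer in one call. Byte-identical output for
#' identical config.
#'
#' @param config a [synthetic_config()].
#' @param grid optional [study_grid()].
#' @return List: `config`, `community`, `records`, `truth`, `lookups`,
#'   `countries`, `gazetteer`.
#' @export
generate_dataset <- function(config, grid = NULL) {
  community <- generate_community(config)
  gen <- generate_records(community, config, grid = grid)
  lookups <- generate_lookups(community, config)
  list(config = config, community = community, records = gen$records,
       truth = gen$truth, cells = gen$cells, lookups = lookups,
       countries = gen$countries, gazetteer = gen$gazetteer)
}

#' Summarise the ground-truth ledger
#'
#' Planted counts per error class (overall and per region) and the true
#' per-cell richness implied by the ledger; the oracle tables the test
#' suite checks filters against.
#'
#' @param truth a ledger tibble from [generate_records()].
#' @return List with `class_counts` (class, region, n) and `cell_truth`
#'   (cell_id_true, region, band_true, n_records, richness_sampled).
#' @export
truth_summary <- function(truth) {
  err_cols <- grep("^err_", names(truth), value = TRUE)
  class_counts <- truth |>
    tidyr::pivot_longer(dplyr::all_of(err_cols), names_to = "class",
                        values_to = "planted") |>
    dplyr::group_by(.data$class, .data$region) |>
    dplyr::summarise(n = sum(.data$planted), .groups = "drop")
  cell_truth <- truth |>
    dplyr::group_by(.data$cell_id_true, .data$region, .data$band_true) |>
    dplyr::summarise(n_records = dplyr::n(),
                     richness_sampled = dplyr::n_distinct(.data$species_true),
                     .groups = "drop")
  list(class_counts = class_counts, cell_truth = cell_truth)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the canonical occurrence CSV, the truth ledger, per-source lookup
#' CSVs, the country-rectangle CSV and the gazetteer CSV.
#'
#' @param sim a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_occurrences(sim$records, file.path(dir, "occurrences.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(sim$countries, file.path(dir, "countries.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(sim$gazetteer, file.path(dir, "gazetteer.csv"), na = "",
                   progress = FALSE)
  for (src in names(sim$lookups)) {
    write_taxon_lookup(sim$lookups[[src]],
                       file.path(dir, paste0("lookup_", src, ".csv")))
  }
  invisible(dir)
}
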
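test_that("the projection is equal-area against independent ellipsoid integration", {
  a <- 6378137; e2 <- 0.00669437999014
  ellipsoid_area <- function(lon1, lon2, lat1, lat2) {
    f <- function(phi) cos(phi) / (1 - e2 * sin(phi)^2)^2
    (lon2 - lon1) * pi / 180 * a^2 * (1 - e2) *
      stats::integrate(f, lat1 * pi / 180, lat2 * pi / 180,
                       rel.tol = 1e-12)$value
  }
  patches <- list(c(-120, -100, 25, 35), c(0, 10, 55, 70), c(140, 170, 75, 85))
  for (p in patches) {
    p1 <- ease2_project(p[1], p[3])
    p2 <- ease2_project(p[2], p[4])
    expect_equal((p2$x - p1$x) * (p2$y - p1$y),
                 ellipsoid_area(p[1], p[2], p[3], p[4]), tolerance = 1e-8)
  }
})

test_that("projection round-trips and the study area spans 49 grid rows", {
  lon <- c(-170.5, -77.3, 0, 12.57, 151.2)
  lat <- c(21.1, 38.9, 50, 55.68, 83.8)
  p <- ease2_project(lon, lat)
  inv <- ease2_inverse(p$x, p$y)
  expect_equal(inv$lon, lon, tolerance = 1e-7)
  expect_equal(inv$lat, lat, tolerance = 1e-7)
  g <- study_grid()
  # 20-90 deg N is 48.4 cell rows of 100 km -> 49 bands
  expect_equal((g$y_top - g$origin[2]) / g$cell_size_m, 48.41, tolerance = 0.01)
})

test_that("fossil and date filters implement the record-level rules", {
  recs <- make_records(2, basisOfRecord = c("FossilSpecimen", "PreservedSpecimen"))
  res <- filter_fossil(recs)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$basisOfRecord, "PreservedSpecimen")
  none <- filter_fossil(make_records(3))
  expect_equal(nrow(none$removed), 0)

  dat <- make_records(4,
    eventDate = c("1985-06-15", "1985-13-02", NA, "1985-06-15"),
    year = c(1985L, 1985L, NA, 3000L))
  res <- filter_dates(dat)
  expect_setequal(res$removed$record_id, c("r002", "r004"))  # bad month, future
  expect_true("r003" %in% res$kept$record_id)                # undated records survive
})

test_that("coordinate rules remove equal, zero, integer, missing and southern points", {
  recs <- make_records(6,
    decimalLatitude  = c(45.0, 52.37, 45.0, 45.5, 19.99, NA),
    decimalLongitude = c(45.0, 0.0,  -3.0, -3.0, 10.5,  2.2))
  res <- filter_coordinates(recs, min_latitude = 20)
  expect_setequal(res$removed$record_id,
                  c("r001", "r002", "r003", "r005", "r006"))
  expect_equal(res$kept$record_id, "r004")  # one fractional coordinate -> kept
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(recs))
  # pair mode keeps a single zero coordinate
  res2 <- filter_coordinates(make_records(1, decimalLatitude = 52.37,
                                          decimalLongitude = 0.0),
                             zero_rule = "pair")
  expect_equal(nrow(res2$removed), 0)
})

test_that("country mismatch respects the buffer and missing codes", {
  countries <- tibble::tibble(countryCode = "E1", lon_min = 0, lon_max = 10,
                              lat_min = 40, lat_max = 50)
  recs <- make_records(5,
    countryCode = c("E1", "E1", "E1", NA, "ZZ"),
    decimalLatitude = c(45.1, 50.05, 50.5, 45.1, 45.1),
    decimalLongitude = c(5.3, 5.3, 5.3, 5.3, 5.3))
  res <- filter_country_mismatch(recs, countries, buffer_deg = 0.1)
  expect_equal(res$removed$record_id, "r003")        # 0.5 deg outside
  expect_true(all(c("r001", "r002", "r004", "r005") %in% res$kept$record_id))
  expect_equal(res$report$n_flagged[res$report$rule == "country_unmatchable"], 1L)
})

test_that("gazetteer proximity removes centroid-planted points only", {
  gaz <- tibble::tibble(label = "centroid_E1", lat = 53.5, lon = 30,
                        radius_km = 1, kind = "country_centroid")
  recs <- make_records(2, decimalLatitude = c(53.5, 53.6),
                       decimalLongitude = c(30, 30.4))
  res <- filter_gazetteer(recs, gaz)
  expect_equal(res$removed$record_id, "r001")
  expect_equal(res$kept$record_id, "r002")
})

test_that("rank filter keeps species and below, judging missing ranks by the name", {
  recs <- make_records(5,
    scientificName = c("Bryum argenteum", "Bryum", "Bryum argenteum",
                       "Bryum argenteum var. lanatum", "Bryum"),
    taxonRank = c("species", "genus", NA, "variety", NA))
  res <- filter_rank(recs)
  expect_setequal(res$kept$record_id, c("r001", "r003", "r004"))
  expect_setequal(res$removed$record_id, c("r002", "r005"))
})

test_that("cell assignment is deterministic, half-open and numbered northwards", {
  g <- study_grid()
  # two points ~1 km apart near a cell centre share a cell
  centre <- ease2_inverse(g$origin[1] + 2000.5 * g$cell_size_m,
                          g$origin[2] + 10.5 * g$cell_size_m)
  nearby <- ease2_inverse(g$origin[1] + 2000.5 * g$cell_size_m + 900,
                          g$origin[2] + 10.5 * g$cell_size_m + 400)
  recs <- make_records(2, decimalLatitude = c(centre$lat, nearby$lat),
                       decimalLongitude = c(centre$lon, nearby$lon))
  res <- assign_cells(recs, g)
  expect_equal(res$records$cell_id[1], res$records$cell_id[2])

  # a point exactly on a cell edge goes to the higher-index cell
  edge <- ease2_inverse(g$origin[1] + 2001 * g$cell_size_m,
                        g$origin[2] + 10.5 * g$cell_size_m)
  on_edge <- assign_cells(make_records(1, decimalLatitude = edge$lat,
                                       decimalLongitude = edge$lon), g)
  expect_match(on_edge$records$cell_id, "^x2001_")

  # monotone northwards band numbering
  two <- assign_cells(make_records(2, decimalLatitude = c(25, 70),
                                   decimalLongitude = c(10, 10)), g)
  expect_lt(two$records$band[1], two$records$band[2])
  expect_equal(two$records$region, rep("EuropeNAfrica", 2))

  # south of the study area -> out of grid, counted
  out <- assign_cells(make_records(1, decimalLatitude = 10,
                                   decimalLongitude = 10), g)
  expect_equal(nrow(out$records), 0)
  expect_equal(out$report$n_flagged, 1L)
})

test_that("the pre-processing chain partitions input and is order-independent", {
  sim <- generate_dataset(clean_config(seed = 9, n_records = 1500,
                                       p_zero_coord = 0.02, p_fossil = 0.03,
                                       p_invalid_date = 0.02,
                                       p_integer_coord = 0.02))
  g <- study_grid()
  pre <- preprocess(sim$records, g, countries = sim$countries,
                    gazetteer = sim$gazetteer)
  expect_equal(nrow(pre$records) + nrow(pre$removed), nrow(sim$records))

  # record-level predicates: any application order yields the same kept set
  f1 <- filter_fossil(sim$records)
  f2 <- filter_dates(f1$kept)
  f3 <- filter_coordinates(f2$kept)
  g1 <- filter_coordinates(sim$records)
  g2 <- filter_fossil(g1$kept)
  g3 <- filter_dates(g2$kept)
  expect_setequal(f3$kept$record_id, g3$kept$record_id)
})

test_that("filters recover planted classes exactly on targeted synthetic data", {
  sim <- generate_dataset(clean_config(seed = 21, n_records = 2000,
                                       p_fossil = 0.05))
  res <- filter_fossil(sim$records)
  expect_setequal(res$removed$record_id,
                  sim$truth$record_id[sim$truth$err_fossil])

  sim2 <- generate_dataset(clean_config(seed = 22, n_records = 2000,
                                        p_centroid = 0.04))
  res2 <- filter_gazetteer(sim2$records, sim2$gazetteer)
  expect_setequal(res2$removed$record_id,
                  sim2$truth$record_id[sim2$truth$err_centroid])
})
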
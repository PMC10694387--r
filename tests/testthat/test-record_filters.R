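test_that("duplicate keys with and without collector behave as defined", {
  recs <- make_records(2, scientificName = c("Bryum argenteum", "Bryum argenteum"),
                       recordedBy = c("Smith", "Jones"))
  recs$acceptedName <- recs$scientificName
  no_coll <- dedupe(recs, duplicate_key(collector = FALSE))
  expect_equal(nrow(no_coll$kept), 1)
  expect_equal(no_coll$kept$record_id, "r001")  # first in input order
  with_coll <- dedupe(recs, duplicate_key(collector = TRUE))
  expect_equal(nrow(with_coll$kept), 2)
})

test_that("dedupe is idempotent, order-invariant in count, and missing keys block merging", {
  recs <- make_records(6,
    scientificName = rep(c("Bryum argenteum", "Tortula muralis"), 3),
    eventDate = c("1985-06-15", "1985-06-15", "1985-06-15",
                  "1990-01-01", NA, NA))
  recs$acceptedName <- recs$scientificName
  once <- dedupe(recs)
  twice <- dedupe(once$kept)
  expect_equal(once$kept$record_id, twice$kept$record_id)
  expect_equal(nrow(twice$removed), 0)
  # rows 5 and 6 miss eventDate -> singletons, never merged
  expect_true(all(c("r005", "r006") %in% once$kept$record_id))

  shuffled <- recs[c(4, 2, 6, 1, 3, 5), ]
  expect_equal(nrow(dedupe(shuffled)$kept), nrow(once$kept))
})

test_that("dedupe kept-count equals the planted duplicate groups", {
  sim <- generate_dataset(clean_config(seed = 31, n_records = 2500,
                                       duplicate_rate = 0.25))
  recs <- sim$records
  recs$acceptedName <- recs$scientificName
  res <- dedupe(recs)
  expect_equal(nrow(res$kept), length(unique(sim$truth$duplicate_group)))

  nodup <- generate_dataset(clean_config(seed = 32, n_records = 800))
  expect_equal(anyDuplicated(nodup$truth$duplicate_group), 0)
})

test_that("basis filter matches values case- and format-insensitively", {
  recs <- make_records(3, basisOfRecord = c("PRESERVED_SPECIMEN",
                                            "HumanObservation",
                                            "preservedspecimen"))
  res <- filter_basis(recs, "PreservedSpecimen")
  expect_setequal(res$kept$record_id, c("r001", "r003"))
  all_vals <- filter_basis(recs, unique(recs$basisOfRecord))
  expect_equal(nrow(all_vals$removed), 0)
})

test_that("temporal windows implement all five standard variants and nest", {
  recs <- make_records(4, year = c(1599L, 1985L, 1995L, NA))
  expect_false("r001" %in% filter_temporal(recs, 1600, require_year = TRUE)$kept$record_id)
  expect_false("r004" %in% filter_temporal(recs, 1600, require_year = TRUE)$kept$record_id)
  expect_true("r002" %in% filter_temporal(recs, 1970, 2000)$kept$record_id)
  expect_false("r002" %in% filter_temporal(recs, 1990)$kept$record_id)
  expect_true("r004" %in% filter_temporal(recs, 1990)$kept$record_id)  # undated kept
  expect_error(filter_temporal(recs, 2000, 1990), "min_year")

  sim <- generate_dataset(clean_config(seed = 33, n_records = 1200,
                                       p_missing_date = 0.05))
  recs2 <- sim$records
  ids <- function(...) filter_temporal(recs2, ...)$kept$record_id
  k90 <- ids(1990); k70 <- ids(1970); k00 <- ids(1900)
  k16 <- ids(1600, require_year = TRUE)
  expect_true(all(k90 %in% k70))
  expect_true(all(k70 %in% k00))
  expect_true(all(k16 %in% k00))
})

test_that("scenarios apply stages in order with deduplication last", {
  sim <- generate_dataset(clean_config(seed = 34, n_records = 1500,
                                       duplicate_rate = 0.2,
                                       basis_mix = c(PreservedSpecimen = 0.5,
                                                     HumanObservation = 0.5)))
  recs <- sim$records
  recs$acceptedName <- recs$scientificName

  sc <- curation_scenario("date-specim", basis_allowed = "PreservedSpecimen")
  res <- apply_scenario(recs, sc)
  expect_equal(res$report$stage, c("taxonomy", "basis", "dedupe"))
  expect_lte(nrow(res$records), nrow(recs))
  expect_equal(nrow(res$records) + nrow(res$removed), nrow(recs))

  # date-specim == basis filter then dedupe on name+coords+date
  manual <- dedupe(filter_basis(recs, "PreservedSpecimen")$kept)
  expect_setequal(res$records$record_id, manual$kept$record_id)

  expect_error(apply_scenario(recs, curation_scenario("x", taxonomy_source = "Nope")),
               "unknown taxonomy source")
})

test_that("per-cell discard proportions match hand counts and edge cases", {
  before <- tibble::tibble(cell_id = c("c1", "c1", "c1", "c2", "c2"),
                           acceptedName = c("A", "A", "B", "C", "D"))
  after <- tibble::tibble(cell_id = c("c1", "c1"), acceptedName = c("A", "A"))
  d <- discard_proportions(before, after)
  expect_equal(d$prop_records_discarded[d$cell_id == "c1"], 1 - 2 / 3)
  expect_equal(d$prop_species_discarded[d$cell_id == "c1"], 1 - 1 / 2)
  expect_equal(d$prop_records_discarded[d$cell_id == "c2"], 1)  # absent cell

  same <- discard_proportions(before, before)
  expect_true(all(same$prop_records_discarded == 0))
  expect_true(all(same$prop_species_discarded == 0))
  expect_warning(discard_proportions(after, before), "omitted")
})
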
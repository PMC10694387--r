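test_that("name normalisation strips authorship, rank markers and case noise", {
  expect_equal(as.character(normalise_name("Bryum argenteum Hedw.")),
               "Bryum argenteum")
  expect_equal(as.character(
    normalise_name("Bryum argenteum var. lanatum (P.Beauv.) Hampe")),
    "Bryum argenteum")
  expect_equal(as.character(normalise_name("bryum  ARGENTEUM")),
               "Bryum argenteum")
  out <- normalise_name(c("Bryum", "Bryum argenteum"))
  expect_equal(attr(out, "uninomial"), c(TRUE, FALSE))
  expect_equal(as.character(out)[1], "Bryum")  # uninomials pass unchanged
})

test_that("standardisation matches exactly, then fuzzily, with ties unresolved", {
  lk <- tiny_lookup(list(c("Bryum argenteum", "Bryum argenteum", "accepted"),
                         c("Bryum argentum", "Bryum argenteum", "synonym"),
                         c("Tortula muralis", "Tortula muralis", "accepted")))
  std <- standardise(c("Bryum argenteum Hedw.", "Weissia controversa"), lk)
  expect_equal(std$accepted_name[1], "Bryum argenteum")
  expect_equal(std$status[2], "no_match")

  fz <- tiny_lookup(list(c("Bryum argenteum", "Bryum argenteum", "accepted")),
                    match_policy = "fuzzy", max_distance = 1)
  std_fz <- standardise("Bryum argentum", fz)  # one-letter typo
  expect_equal(std_fz$accepted_name, "Bryum argenteum")

  # two neighbours at equal distance 1 -> tie -> unresolved
  tie <- tiny_lookup(list(c("Bryum alba", "Bryum alba", "accepted"),
                          c("Bryum alca", "Bryum alca", "accepted")),
                     match_policy = "fuzzy", max_distance = 1)
  std_tie <- standardise("Bryum alia", tie)
  expect_equal(std_tie$status, "unresolved")
  expect_true(is.na(std_tie$accepted_name))
})

# five hand-enumerable sources used for the consensus checks
consensus_maps <- function() {
  list(
    s1 = tiny_map(list(c("Bryum alpha", "Bryum alpha"),
                       c("Bryum beta", "Bryum beta"),
                       c("Bryum gamma", "Bryum gamma"),
                       c("Bryum zeta", "Bryum aa"))),
    s2 = tiny_map(list(c("Bryum alpha", "Bryum alpha"),
                       c("Bryum beta", "Bryum beta"),
                       c("Bryum gamma", "Bryum gamma"),
                       c("Bryum zeta", "Bryum aa"))),
    s3 = tiny_map(list(c("Bryum alpha", "Bryum alpha"),
                       c("Bryum gamma", "Bryum gamma"),
                       c("Bryum delta", NA),
                       c("Bryum zeta", "Bryum bb"),
                       c("Weissia w", "Bryum aa"))),
    s4 = tiny_map(list(c("Bryum gamma", "Bryum gamma"),
                       c("Bryum delta", NA),
                       c("Bryum zeta", "Bryum bb"),
                       c("Weissia w", "Bryum aa"),
                       c("Tortula t", "Bryum bb"))),
    s5 = tiny_map(list(c("Bryum gamma", "Bryum gamma"),
                       c("Bryum delta", NA),
                       c("Tortula t", "Bryum bb"))))
}

test_that("consensus voting matches the hand count and is monotone in min_votes", {
  maps <- consensus_maps()
  # hand count of accepted-name votes:
  #   alpha s1,s2,s3 = 3; beta s1,s2 = 2; gamma all = 5;
  #   aa s1,s2 (via zeta) + s3,s4 (via Weissia) = 4; bb s3,s4,s5 = 3;
  #   delta unresolved everywhere = 0
  cons <- build_consensus(maps, min_votes = 3)
  expect_setequal(cons$accepted_name,
                  c("Bryum alpha", "Bryum gamma", "Bryum aa", "Bryum bb"))
  expect_equal(cons$votes[cons$accepted_name == "Bryum gamma"], 5L)
  expect_equal(cons$votes[cons$accepted_name == "Bryum aa"], 4L)

  for (k in 4:5) {
    expect_true(all(build_consensus(maps, min_votes = k)$accepted_name %in%
                      build_consensus(maps, min_votes = k - 1)$accepted_name))
  }
  expect_setequal(build_consensus(maps, min_votes = 5)$accepted_name,
                  "Bryum gamma")
  expect_error(build_consensus(maps[1:2], min_votes = 3), "min_votes")
})

test_that("consensus annotation keeps reachable names and flags vote ties", {
  maps <- consensus_maps()
  cons <- build_consensus(maps, min_votes = 3)
  recs <- make_records(3, scientificName = c("Bryum alpha", "Bryum beta",
                                             "Bryum zeta"))
  res <- apply_consensus(recs, maps, cons)
  # beta resolves only to a non-consensus name -> dropped
  expect_equal(res$removed$scientificName, "Bryum beta")
  expect_equal(res$records$acceptedName[res$records$scientificName == "Bryum alpha"],
               "Bryum alpha")
  # zeta: 2 sources say aa, 2 say bb, both in consensus -> lexicographic, flagged
  zeta <- res$records[res$records$scientificName == "Bryum zeta", ]
  expect_equal(zeta$acceptedName, "Bryum aa")
  expect_true(zeta$name_tie)
  expect_equal(res$report$n_in, res$report$n_removed + res$report$n_kept)
})

test_that("per-cell richness deltas against the consensus match a hand count", {
  mk <- function(cell, sp) tibble::tibble(cell_id = cell, region = "EuropeNAfrica",
                                          acceptedName = sp)
  src <- dplyr::bind_rows(mk("c1", c("A", "B", "C")), mk("c2", c("A")),
                          mk("c3", c("A", "B")))
  cns <- dplyr::bind_rows(mk("c1", c("A", "B")), mk("c2", c("A")),
                          mk("c4", c("Z")))
  res <- cell_richness_delta(src, cns)
  d <- res$deltas
  expect_equal(d$klass[d$cell_id == "c1"], "I")   # 3 vs 2
  expect_equal(d$klass[d$cell_id == "c2"], "E")   # 1 vs 1
  expect_equal(d$klass[d$cell_id == "c3"], "I")   # 2 vs 0 (absent -> 0)
  expect_equal(d$klass[d$cell_id == "c4"], "D")   # 0 vs 1
  props <- res$proportions
  expect_equal(sum(props$proportion), 1)

  ident <- cell_richness_delta(src, src)
  expect_true(all(ident$deltas$klass == "E"))
})
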
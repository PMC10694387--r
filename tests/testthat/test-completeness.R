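test_that("exact rarefaction equals the analytic examples and enumeration", {
  expect_equal(rarefaction_exact(c(A = 2, B = 1), 2), 5 / 3)
  expect_equal(rarefaction_exact(c(3, 2, 1), 6), 3)          # m = N -> S_obs
  expect_equal(rarefaction_exact(c(3, 2, 1), 0), 0)
  expect_equal(rarefaction_exact(7, 3), 1)                   # single species
  expect_error(rarefaction_exact(c(2, 1), 4), "m must lie")

  set.seed(101)
  for (i in 1:25) {
    s <- sample(1:4, 1)
    counts <- rmultinom(1, sample(s:10, 1), rep(1, s))[, 1]
    counts <- counts[counts > 0]
    n_tot <- sum(counts)
    for (m in 0:n_tot) {
      expect_equal(rarefaction_exact(counts, m), rarefy_enum(counts, m),
                   tolerance = 1e-12)
    }
  }
})

test_that("rarefaction agrees with an independent community-ecology implementation", {
  set.seed(7)
  counts <- as.integer(table(sample(letters[1:12], 300, replace = TRUE,
                                    prob = c(8, 5, 4, 3, 3, 2, 2, 1, 1, 1, 1, 1))))
  # vegan's individual-based reference: rarefy at m = 1..N
  ours <- rarefaction_exact(counts, seq_len(sum(counts)))
  ref <- suppressWarnings(vapply(seq_len(sum(counts)), function(m)
    as.numeric(vegan::rarefy(counts, m)), numeric(1)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("accumulation curves are anchored, monotone and concave", {
  small <- build_sac(c(2, 2, 1))
  expect_equal(small$m, 1:5)                     # n_points >= N -> every m
  expect_equal(small$e_s[5], 3)                  # last point = (N, S_obs)

  set.seed(11)
  for (i in 1:10) {
    counts <- rmultinom(1, 12, rep(1, 4))[, 1]
    counts <- counts[counts > 0]
    curve <- build_sac(counts)
    expect_true(all(diff(curve$e_s) >= -1e-12))
    expect_true(all(diff(diff(curve$e_s)) <= 1e-12))
    expect_equal(curve$e_s[nrow(curve)], length(counts))
    # against brute-force subset means
    for (m in curve$m) {
      expect_equal(curve$e_s[curve$m == m], rarefy_enum(counts, m),
                   tolerance = 1e-12)
    }
  }
})

test_that("the rational model recovers exact curves and handles flat ones", {
  m <- seq(1, 400, length.out = 60)
  for (par in list(c(0, 2, 0.02), c(1, 5, 0.1), c(0.5, 0.8, 0.004))) {
    curve <- tibble::tibble(m = m, e_s = (par[1] + par[2] * m) / (1 + par[3] * m))
    fit <- fit_rational(curve)
    expect_true(fit$ok)
    expect_equal(fit$asymptote, par[2] / par[3], tolerance = 1e-6)
  }
  flat <- fit_rational(tibble::tibble(m = 1:10, e_s = rep(4, 10)))
  expect_true(flat$flat)
  expect_equal(flat$asymptote, 4)
  expect_false(fit_rational(tibble::tibble(m = 1:2, e_s = c(1, 2)))$ok)
})

test_that("terminal slope reads species gained per record at the curve end", {
  two <- tibble::tibble(m = c(90, 100), e_s = c(20, 21))
  expect_equal(terminal_slope(two), 0.1)
  flat <- tibble::tibble(m = seq(10, 100, 10), e_s = rep(12, 10))
  expect_equal(terminal_slope(flat), 0)
  # concavity: the terminal slope never exceeds the mean slope S_obs / N
  set.seed(13)
  for (i in 1:10) {
    counts <- rmultinom(1, 40, rep(1, 8))[, 1]
    counts <- counts[counts > 0]
    curve <- build_sac(counts)
    expect_lte(terminal_slope(curve), length(counts) / sum(counts) + 1e-12)
  }
})

test_that("well-sampled classification is inclusive at every boundary", {
  base <- tibble::tibble(cell_id = "c", band = 1L, region = "EuropeNAfrica",
                         n_records = 100L, s_obs = 20L, predicted = 28.6,
                         completeness_pct = 70, slope = 0.1, ratio = 5,
                         fit_ok = TRUE, capped = FALSE)
  expect_true(classify_well_sampled(base)$well_sampled)
  flip <- function(field, value) {
    x <- base; x[[field]] <- value
    classify_well_sampled(x)$well_sampled
  }
  expect_false(flip("n_records", 99L))
  expect_false(flip("completeness_pct", 69.9))
  expect_false(flip("ratio", 4.99))
  expect_false(flip("slope", 0.2))
  expect_equal(classify_well_sampled(base)$criteria_passed, 4)
})

test_that("per-cell metrics saturate on densely sampled synthetic cells", {
  # effort chosen so nearly every cell sees each of its species >= 5 times
  sim <- generate_dataset(clean_config(seed = 41, n_records = 35000,
                                       base_richness = 5, slope_below = 1,
                                       slope_above = -1,
                                       cells_per_band = 1, effort_sd = 0.2))
  recs <- sim$records
  # judge completeness on the true species identity from the ledger
  recs$acceptedName <-
    sim$truth$species_true[match(recs$record_id, sim$truth$record_id)]
  g <- study_grid()
  cells <- assign_cells(recs, g)
  met <- completeness_metrics(cells$records)
  expect_true(all(met$ratio >= 1))
  expect_true(all(met$slope >= -1e-12, na.rm = TRUE))
  expect_true(all(met$completeness_pct <= 100, na.rm = TRUE))
  # saturated effort: nearly all cells nearly complete
  expect_gte(mean(met$completeness_pct >= 90, na.rm = TRUE), 0.95)
  # predicted richness at least observed when the fit is unflagged/uncapped
  unc <- met[met$fit_ok & !met$capped, ]
  expect_true(all(unc$predicted >= unc$s_obs - 1e-9))
})

test_that("counting qualifying filter datasets per cell sums the flags", {
  m1 <- tibble::tibble(cell_id = c("a", "b"), well_sampled = c(TRUE, FALSE))
  m2 <- tibble::tibble(cell_id = c("a", "b"), well_sampled = c(TRUE, TRUE))
  out <- well_sampled_across(list(f1 = m1, f2 = m2))
  expect_equal(out$n_filters_well_sampled[out$cell_id == "a"], 2L)
  expect_equal(out$n_filters_well_sampled[out$cell_id == "b"], 1L)
})
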
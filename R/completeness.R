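# Per-cell inventory completeness: exact (analytic) rarefaction of the
# species accumulation curve, a rational-function asymptotic richness
# estimator, the terminal slope of the curve, and the well-sampled-cell
# classification.

#' Exact rarefaction: expected richness in a subsample
#'
#' Analytic hypergeometric expectation of the number of species observed in
#' a uniform random subsample of `m` of the `N` records:
#' `E[S(m)] = S_obs - sum_i C(N - N_i, m) / C(N, m)`. Computed in log-space,
#' so it is stable for large `N`.
#'
#' @param species_counts integer vector of records per species (`N_i >= 1`);
#'   names optional.
#' @param m integer vector of subsample sizes, each in `[0, N]`.
#' @return Numeric vector `E[S(m)]`, one element per `m`.
#' @export
#' @examples
#' rarefaction_exact(c(A = 2, B = 1), 2) # 5/3
rarefaction_exact <- function(species_counts, m) {
  counts <- as.numeric(species_counts)
  stopifnot(length(counts) > 0, all(counts >= 1), all(counts == round(counts)))
  n_tot <- sum(counts)
  if (any(m < 0 | m > n_tot)) {
    stop("m must lie in [0, N] with N = ", n_tot, call. = FALSE)
  }
  s_obs <- length(counts)
  vapply(m, function(mm) {
    if (mm == 0) return(0)
    # lchoose(n, k) is -Inf for k > n, so absent terms vanish cleanly
    lg <- lchoose(n_tot - counts, mm) - lchoose(n_tot, mm)
    s_obs - sum(exp(lg))
  }, numeric(1))
}

#' Build a species accumulation curve for one inventory
#'
#' Evaluates exact rarefaction at `n_points` subsample sizes spanning
#' `1..N` (always including 1 and `N`). The curve is non-decreasing and
#' concave, and ends exactly at the observed richness.
#'
#' @param species_counts integer vector of records per species.
#' @param n_points number of evaluation points (default `min(N, 100)`).
#' @return Tibble with columns `m` and `e_s`, of class `sac_curve`.
#' @export
build_sac <- function(species_counts, n_points = NULL) {
  n_tot <- sum(species_counts)
  stopifnot(n_tot >= 1)
  if (is.null(n_points)) n_points <- min(n_tot, 100)
  ms <- sort(unique(c(1, round(seq(1, n_tot, length.out = min(n_tot, n_points))),
                      n_tot)))
  out <- tibble::tibble(m = as.numeric(ms),
                        e_s = rarefaction_exact(species_counts, ms))
  class(out) <- c("sac_curve", class(out))
  out
}

#' Fit the rational asymptotic model to an accumulation curve
#'
#' Least-squares fit of `S(m) = (a + b m) / (1 + c m)`; the estimated
#' asymptotic richness is `b / c`. Solved deterministically by
#' Levenberg-Marquardt on the true residuals (with `c` bounded positive so
#' the asymptote is finite), started from the linearised solution of
#' `S = a + b m - c (m S)` when that is well-behaved and otherwise from a
#' Michaelis-Menten-style half-saturation guess; the rearranged linear
#' system alone is badly conditioned for near-saturated curves. A flat
#' curve is its own asymptote. Non-converging fits are flagged unusable.
#'
#' @param curve a [build_sac()] curve (or any tibble with `m`, `e_s`);
#'   at least 3 points unless flat.
#' @return A `rational_fit` list: `a`, `b`, `c`, `asymptote`, `ok`, `flat`.
#' @export
fit_rational <- function(curve) {
  m <- curve$m
  s <- curve$e_s
  if (diff(range(s)) < 1e-12) {
    return(structure(list(a = s[1], b = NA_real_, c = NA_real_,
                          asymptote = s[1], ok = TRUE, flat = TRUE),
                     class = "rational_fit"))
  }
  bad <- structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                        asymptote = NA_real_, ok = FALSE, flat = FALSE),
                   class = "rational_fit")
  if (length(m) < 3) return(bad)
  rss <- function(p) {
    den <- 1 + p$c * m
    if (any(den <= 0)) return(Inf)
    sum((s - (p$a + p$b * m) / den)^2)
  }
  # linearised start, used only when it implies a finite positive asymptote
  start <- NULL
  qx <- qr(cbind(1, m, -m * s))
  if (qx$rank == 3) {
    beta <- unname(qr.coef(qx, s))
    if (all(is.finite(beta)) && beta[3] > 0 && all(1 + beta[3] * m > 0)) {
      start <- list(a = beta[1], b = beta[2], c = beta[3])
    }
  }
  lin <- start
  # an exactly rational curve is solved by the linear system already (and
  # would give nls a singular zero-residual gradient)
  if (!is.null(start) && rss(start) <= 1e-16 * sum(s^2)) {
    return(structure(list(a = start$a, b = start$b, c = start$c,
                          asymptote = start$b / start$c, ok = TRUE,
                          flat = FALSE),
                     class = "rational_fit"))
  }
  if (is.null(start)) {
    s_max <- max(s)
    half <- m[which(s >= s_max / 2)[1]]
    c0 <- 1 / max(half, 1)
    start <- list(a = 0, b = 1.05 * s_max * c0, c = c0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(e_s ~ (a + b * m) / (1 + c * m),
                      data = data.frame(m = m, e_s = s),
                      start = start,
                      lower = c(a = -Inf, b = -Inf, c = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  cf <- if (!is.null(fit)) as.list(stats::coef(fit)) else lin
  if (is.null(cf)) return(bad)
  # keep whichever of LM solution / linearised solution fits better
  if (!is.null(lin) && rss(lin) < rss(cf)) cf <- lin
  ok <- all(is.finite(unlist(cf))) && cf[["c"]] > 0
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                 asymptote = if (ok) cf[["b"]] / cf[["c"]] else NA_real_,
                 ok = ok, flat = FALSE),
            class = "rational_fit")
}

#' Terminal slope of an accumulation curve
#'
#' Least-squares slope of expected richness against subsample size over the
#' last `tail_fraction` of the effort range (at minimum the final two
#' points): species gained per additional record at the end of the curve.
#'
#' @param curve a [build_sac()] curve with at least 2 points.
#' @param tail_fraction fraction of the `m` range forming the tail
#'   (default 0.1).
#' @return Numeric slope (species per record).
#' @export
terminal_slope <- function(curve, tail_fraction = 0.1) {
  m <- curve$m
  s <- curve$e_s
  stopifnot(length(m) >= 2)
  cut <- max(m) - tail_fraction * (max(m) - min(m))
  idx <- which(m >= cut)
  if (length(idx) < 2) idx <- (length(m) - 1):length(m)
  mm <- m[idx]; ss <- s[idx]
  unname(stats::coef(stats::lm.fit(cbind(1, mm), ss))[2])
}

#' Well-sampled thresholds
#'
#' The four survey-quality criteria a cell must pass, all boundaries
#' inclusive: at least `min_records` records, inventory completeness at
#' least `min_completeness_pct`, a records/richness ratio of at least
#' `min_ratio`, and a terminal slope of at most `max_slope` (one new
#' species per ten further records at the default 0.1).
#'
#' @param min_records,min_completeness_pct,min_ratio,max_slope thresholds.
#' @return A named list of thresholds.
#' @export
well_sampled_thresholds <- function(min_records = 100,
                                    min_completeness_pct = 70,
                                    min_ratio = 5,
                                    max_slope = 0.1) {
  stopifnot(min_records > 0, min_completeness_pct > 0, min_ratio > 0,
            max_slope > 0)
  list(min_records = min_records,
       min_completeness_pct = min_completeness_pct,
       min_ratio = min_ratio,
       max_slope = max_slope)
}

#' Per-cell completeness metrics
#'
#' For every grid cell: builds the species accumulation curve by exact
#' rarefaction, estimates asymptotic richness with the rational model
#' (capped completeness flagged when the fitted asymptote falls below the
#' observed richness), measures the terminal slope, and classifies the cell
#' against the well-sampled thresholds. Cells whose rational fit fails are
#' flagged and can never classify as well-sampled.
#'
#' @param records cell-annotated occurrence tibble; species are read from
#'   `species_col`.
#' @param thresholds a [well_sampled_thresholds()] list.
#' @param species_col name column used for richness.
#' @param n_points SAC evaluation points per cell (default `min(N, 100)`).
#' @param tail_fraction tail of the curve used for the terminal slope.
#' @return Tibble, one row per cell: `cell_id`, `band`, `region`,
#'   `n_records`, `s_obs`, `predicted`, `completeness_pct`, `slope`,
#'   `ratio`, `fit_ok`, `capped`, `criteria_passed`, `well_sampled`.
#' @export
completeness_metrics <- function(records,
                                 thresholds = well_sampled_thresholds(),
                                 species_col = "acceptedName",
                                 n_points = NULL,
                                 tail_fraction = 0.1) {
  stopifnot(all(c("cell_id", species_col) %in% names(records)))
  cells <- split(records, records$cell_id)
  rows <- lapply(cells, function(x) {
    counts <- table(x[[species_col]])
    curve <- build_sac(as.integer(counts), n_points = n_points)
    fit <- fit_rational(curve)
    s_obs <- length(counts)
    n_tot <- sum(counts)
    capped <- FALSE
    completeness <- NA_real_
    predicted <- NA_real_
    if (fit$ok) {
      predicted <- fit$asymptote
      completeness <- 100 * s_obs / predicted
      if (completeness > 100) {
        completeness <- 100
        predicted <- s_obs
        capped <- TRUE
      }
    }
    slope <- if (nrow(curve) >= 2) terminal_slope(curve, tail_fraction) else NA_real_
    tibble::tibble(
      cell_id = x$cell_id[1],
      band = if ("band" %in% names(x)) x$band[1] else NA_integer_,
      region = if ("region" %in% names(x)) x$region[1] else NA_character_,
      n_records = n_tot,
      s_obs = s_obs,
      predicted = predicted,
      completeness_pct = completeness,
      slope = slope,
      ratio = n_tot / s_obs,
      fit_ok = fit$ok,
      capped = capped)
  })
  classify_well_sampled(dplyr::bind_rows(rows), thresholds)
}

#' Classify cells against the well-sampled thresholds
#'
#' Adds the per-criterion pass table, the count of criteria passed (0-4)
#' and the final flag (all four pass, boundaries inclusive). Cells with an
#' unusable completeness fit fail the completeness criterion.
#'
#' @param metrics tibble from [completeness_metrics()] (needs `n_records`,
#'   `completeness_pct`, `ratio`, `slope`).
#' @param thresholds a [well_sampled_thresholds()] list.
#' @return `metrics` with `pass_*` columns, `criteria_passed` and
#'   `well_sampled` appended.
#' @export
classify_well_sampled <- function(metrics,
                                  thresholds = well_sampled_thresholds()) {
  m <- dplyr::mutate(
    metrics,
    pass_records = .data$n_records >= thresholds$min_records,
    pass_completeness = !is.na(.data$completeness_pct) &
      .data$completeness_pct >= thresholds$min_completeness_pct,
    pass_ratio = .data$ratio >= thresholds$min_ratio,
    pass_slope = !is.na(.data$slope) & .data$slope <= thresholds$max_slope)
  m$criteria_passed <- rowSums(m[c("pass_records", "pass_completeness",
                                   "pass_ratio", "pass_slope")])
  m$well_sampled <- m$criteria_passed == 4L
  m
}

#' Count, per cell, the filter datasets under which it is well-sampled
#'
#' Given completeness metrics computed under each cleaning-filter dataset,
#' returns for every cell the number of datasets (0 to the number supplied)
#' under which it classifies as well-sampled.
#'
#' @param metrics_list named list of [completeness_metrics()] tibbles, one
#'   per filter dataset.
#' @return Tibble with `cell_id` and `n_filters_well_sampled`.
#' @export
well_sampled_across <- function(metrics_list) {
  dplyr::bind_rows(metrics_list, .id = "filter") |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_filters_well_sampled = sum(.data$well_sampled),
                     .groups = "drop")
}
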
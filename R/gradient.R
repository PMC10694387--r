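# Latitudinal richness gradient: per-band summaries over well-sampled
# cells, single-breakpoint piecewise linear regression estimated by
# exhaustive SSE profiling, and scenario comparison tables.

#' Per-band richness series over well-sampled cells
#'
#' Medians of observed and predicted (asymptotic) richness per latitudinal
#' band, over well-sampled cells only; bands with no well-sampled cell are
#' omitted.
#'
#' @param metrics a [completeness_metrics()] tibble (with `band`, `s_obs`,
#'   `predicted`, `well_sampled`).
#' @param region optional region label to restrict to (default all).
#' @return Tibble: `band`, `n_cells`, `median_observed`,
#'   `median_predicted`, `observed_min`, `observed_max`.
#' @export
band_series <- function(metrics, region = NULL) {
  x <- dplyr::filter(metrics, .data$well_sampled)
  if (!is.null(region)) {
    x <- dplyr::filter(x, .data$region %in% !!region)
  }
  if (nrow(x) == 0) {
    warning("no well-sampled cells in the requested region", call. = FALSE)
    return(tibble::tibble(band = integer(), n_cells = integer(),
                          median_observed = double(),
                          median_predicted = double(),
                          observed_min = double(), observed_max = double()))
  }
  x |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      median_observed = stats::median(.data$s_obs),
      median_predicted = stats::median(.data$predicted, na.rm = TRUE),
      observed_min = min(.data$s_obs),
      observed_max = max(.data$s_obs),
      .groups = "drop") |>
    dplyr::arrange(.data$band)
}

#' Fit a single-breakpoint piecewise linear regression
#'
#' Model `y = b0 + b1 x + b2 (x - psi) 1[x > psi]`, with the breakpoint
#' `psi` estimated by exhaustive profiling: for every candidate on a grid
#' over the interior of the observed `x` values, the two-segment model is
#' fitted by ordinary least squares and the `psi` minimising the SSE is
#' kept. Deterministic and global on its grid, with no initialisation
#' sensitivity. The fit is degenerate when the SSE improvement over a
#' single straight line is negligible (the data carry no breakpoint
#' signal).
#'
#' @param x numeric predictor (band indices, or any affine transform of
#'   them; `psi` is reported on the same scale).
#' @param y numeric response (richness).
#' @param grid_step candidate spacing, as a multiple of the median spacing
#'   of distinct `x` values (default 0.25, i.e. quarter-band resolution for
#'   unit-spaced bands).
#' @param weights optional non-negative case weights.
#' @return A `breakpoint_fit` list: `psi`, `beta0`, `beta1`, `beta2`,
#'   `r_squared`, `sse`, `sse_line`, `degenerate`, `n`.
#' @export
fit_piecewise <- function(x, y, grid_step = 0.25, weights = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(x)) else weights[keep]
  xs <- sort(unique(x))
  few <- length(xs) < 5
  wmean <- sum(w * y) / sum(w)
  tss <- sum(w * (y - wmean)^2)
  line <- stats::lm.wfit(cbind(1, x), y, w)
  sse_line <- sum(w * line$residuals^2)
  if (tss < 1e-12 || few) {
    return(structure(list(psi = NA_real_, beta0 = unname(line$coefficients[1]),
                          beta1 = unname(line$coefficients[2]),
                          beta2 = 0, r_squared = if (tss < 1e-12) NA_real_
                                     else 1 - sse_line / tss,
                          sse = sse_line, sse_line = sse_line,
                          degenerate = TRUE, n = length(x)),
                     class = "breakpoint_fit"))
  }
  step <- grid_step * stats::median(diff(xs))
  cand <- seq(xs[2], xs[length(xs) - 1], by = step)
  sse <- vapply(cand, function(p) {
    z <- pmax(x - p, 0)
    f <- stats::lm.wfit(cbind(1, x, z), y, w)
    sum(w * f$residuals^2)
  }, numeric(1))
  best <- which.min(sse)
  psi <- cand[best]
  z <- pmax(x - psi, 0)
  f <- stats::lm.wfit(cbind(1, x, z), y, w)
  sse_best <- sum(w * f$residuals^2)
  degenerate <- (sse_line - sse_best) < 1e-9 * max(sse_line, .Machine$double.eps)
  structure(list(psi = if (degenerate) NA_real_ else psi,
                 beta0 = unname(f$coefficients[1]),
                 beta1 = unname(f$coefficients[2]),
                 beta2 = unname(f$coefficients[3]),
                 r_squared = 1 - sse_best / tss,
                 sse = sse_best, sse_line = sse_line,
                 degenerate = degenerate, n = length(x)),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<breakpoint_fit> degenerate (no breakpoint signal), n =", x$n, "\n")
  } else {
    cat(sprintf(
      "<breakpoint_fit> psi = %.2f, slopes %.3f / %.3f, R^2 = %.3f, n = %d\n",
      x$psi, x$beta1, x$beta1 + x$beta2, x$r_squared, x$n))
  }
  invisible(x)
}

#' Fit observed and predicted gradients for one band series
#'
#' @param series a [band_series()] tibble.
#' @param grid_step passed to [fit_piecewise()].
#' @return List with `observed` and `predicted` `breakpoint_fit`s (or
#'   `NULL` when the series is too short).
#' @export
fit_band_series <- function(series, grid_step = 0.25) {
  safe_fit <- function(y) {
    if (nrow(series) < 3) return(NULL)
    fit_piecewise(series$band, y, grid_step = grid_step)
  }
  list(observed = safe_fit(series$median_observed),
       predicted = safe_fit(series$median_predicted))
}

#' Compare breakpoints across curation scenarios
#'
#' Builds the scenario-by-region table of observed and predicted richness
#' breakpoints and flags scenario pairs (against the first scenario, the
#' reference) whose observed breakpoints differ by more than
#' `shift_bands`.
#'
#' @param fits nested named list: `fits[[scenario]][[region]]` is a
#'   [fit_band_series()] result; regions may also carry `n_cells`.
#' @param shift_bands flag threshold in bands (default 3).
#' @return Tibble: scenario, region, bp_observed, bp_predicted, r2_observed,
#'   r2_predicted, shifted (vs. the first scenario in the same region).
#' @export
scenario_comparison <- function(fits, shift_bands = 3) {
  rows <- list()
  for (sc in names(fits)) {
    for (rg in names(fits[[sc]])) {
      f <- fits[[sc]][[rg]]
      get <- function(which, fld) {
        v <- f[[which]]
        if (is.null(v)) NA_real_ else v[[fld]]
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        scenario = sc, region = rg,
        bp_observed = get("observed", "psi"),
        bp_predicted = get("predicted", "psi"),
        r2_observed = get("observed", "r_squared"),
        r2_predicted = get("predicted", "r_squared"))
    }
  }
  out <- dplyr::bind_rows(rows)
  ref <- out |>
    dplyr::filter(.data$scenario == names(fits)[1]) |>
    dplyr::select("region", ref_bp = "bp_observed")
  out <- dplyr::left_join(out, ref, by = "region")
  out$shifted <- !is.na(out$bp_observed) & !is.na(out$ref_bp) &
    abs(out$bp_observed - out$ref_bp) > shift_bands
  dplyr::select(out, -"ref_bp")
}
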
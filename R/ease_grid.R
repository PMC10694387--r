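# Cylindrical equal-area projection on the WGS84 ellipsoid with standard
# parallel 30 degrees (the EASE-Grid 2.0 Global parameterisation), plus the
# 100-km study grid built on it. Implemented directly from the authalic-
# latitude formulation; no external projection library is required.

.wgs84 <- list(a = 6378137, e2 = 0.00669437999014)

# authalic q(phi); phi in radians
.ease_q <- function(phi) {
  e2 <- .wgs84$e2
  e <- sqrt(e2)
  s <- sin(phi)
  (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
}

.ease_k0 <- function() {
  e2 <- .wgs84$e2
  phi1 <- 30 * pi / 180
  cos(phi1) / sqrt(1 - e2 * sin(phi1)^2)
}

#' Project WGS84 coordinates to the equal-area study plane
#'
#' Forward cylindrical equal-area projection (standard parallel 30 deg N,
#' WGS84 ellipsoid), the projection family used by the EASE-Grid 2.0 Global
#' tessellation. `x` grows eastwards, `y` northwards, both in metres.
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @return A list with numeric components `x` and `y` (metres).
#' @seealso [ease2_inverse()], [study_grid()]
#' @export
#' @examples
#' ease2_project(0, 30)
ease2_project <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  k0 <- .ease_k0()
  x <- .wgs84$a * k0 * lon * pi / 180
  y <- .wgs84$a * .ease_q(lat * pi / 180) / (2 * k0)
  list(x = x, y = y)
}

#' Inverse equal-area projection back to WGS84 longitude/latitude
#'
#' Inverts [ease2_project()] using the authalic-to-geodetic latitude series.
#'
#' @param x,y numeric vectors, metres in the projected plane.
#' @return A list with numeric components `lon` and `lat` (decimal degrees).
#' @export
ease2_inverse <- function(x, y) {
  stopifnot(length(x) == length(y))
  a <- .wgs84$a
  e2 <- .wgs84$e2
  k0 <- .ease_k0()
  lon <- (x / (a * k0)) * 180 / pi
  q <- 2 * y * k0 / a
  qp <- .ease_q(pi / 2)
  beta <- asin(pmin(1, pmax(-1, q / qp)))
  phi <- beta +
    (e2 / 3 + 31 * e2^2 / 180 + 517 * e2^3 / 5040) * sin(2 * beta) +
    (23 * e2^2 / 360 + 251 * e2^3 / 3780) * sin(4 * beta) +
    (761 * e2^3 / 45360) * sin(6 * beta)
  list(lon = lon, lat = phi * 180 / pi)
}

#' Define the equal-area analysis grid
#'
#' Builds the 100-km equal-area grid over the temperate Northern Hemisphere:
#' square cells in the projected plane, rows dissolved into latitudinal bands
#' numbered from 1 at the southern study limit northwards, and regions cut by
#' meridians. Cells are half-open `[low, high)` intervals in projected x and
#' y; points on the global upper edge belong to the last row.
#'
#' @param cell_size_m cell width in metres (default 100 km).
#' @param n_bands number of latitudinal bands (rows); the default 49 covers
#'   20-90 deg N at 100 km.
#' @param min_latitude southern study limit in decimal degrees (default 20).
#' @param region_breaks interior meridians (degrees) splitting the study area
#'   into `length(region_breaks) + 1` regions, west to east.
#' @param region_labels labels for the regions, west to east.
#' @param origin optional `c(x0, y0)` of the grid origin in metres; by default
#'   x0 is the west edge of the projection and y0 the projected
#'   `min_latitude`.
#' @return An object of class `study_grid`.
#' @export
#' @examples
#' g <- study_grid()
#' g$n_bands
study_grid <- function(cell_size_m = 1e5,
                       n_bands = 49,
                       min_latitude = 20,
                       region_breaks = c(-30, 60),
                       region_labels = c("NorthAmerica", "EuropeNAfrica", "Asia"),
                       origin = NULL) {
  stopifnot(cell_size_m > 0, n_bands >= 1,
            length(region_labels) == length(region_breaks) + 1,
            !is.unsorted(region_breaks))
  if (is.null(origin)) {
    origin <- c(-.wgs84$a * .ease_k0() * pi,
                ease2_project(0, min_latitude)$y)
  }
  structure(
    list(cell_size_m = cell_size_m,
         n_bands = n_bands,
         min_latitude = min_latitude,
         region_breaks = region_breaks,
         region_labels = region_labels,
         origin = origin,
         y_top = ease2_project(0, 90)$y),
    class = "study_grid"
  )
}

#' @export
print.study_grid <- function(x, ...) {
  cat("<study_grid> ", x$cell_size_m / 1000, "-km equal-area cells, ",
      x$n_bands, " bands from ", x$min_latitude, " deg N; regions: ",
      paste(x$region_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# region label from longitude under the grid's meridian rules
.grid_region <- function(grid, lon) {
  idx <- findInterval(lon, grid$region_breaks) + 1L
  grid$region_labels[idx]
}

# latitude interval (southern edges) of one band row; used by the synthetic
# generator to sample inside a given band
.band_y_range <- function(grid, band) {
  y0 <- grid$origin[2]
  lo <- y0 + (band - 1) * grid$cell_size_m
  hi <- pmin(y0 + band * grid$cell_size_m, grid$y_top)
  cbind(lo, hi)
}
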
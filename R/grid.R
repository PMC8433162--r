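#' Regular latitude--longitude analysis grid
#'
#' Builds the grid geometry used by all metrics: cell-centre coordinates, an
#' ocean mask, and cosine-latitude area weights. Only area *fractions* are ever
#' reported, so weights are proportional to `cos(lat) * dlat * dlon`; the exact
#' spherical-cap area is not needed. Weights are zero on land so that land
#' never contributes to area-weighted statistics.
#'
#' @param lat Numeric vector of cell-centre latitudes (degrees, strictly
#'   increasing).
#' @param lon Numeric vector of cell-centre longitudes (degrees); values are
#'   normalised to `[-180, 180)`.
#' @param ocean_mask Logical matrix `length(lat) x length(lon)`; TRUE = ocean.
#'   Default: all ocean.
#'
#' @return An object of class `plankton_grid`: a list with `lat`, `lon`,
#'   `area_weight` (matrix, zero on land) and `ocean_mask`.
#' @export
#' @examples
#' g <- make_grid(lat = seq(-80, 80, by = 20), lon = seq(-170, 170, by = 20))
#' sum(g$area_weight)
make_grid <- function(lat, lon, ocean_mask = NULL) {
  stopifnot(is.numeric(lat), is.numeric(lon), length(lat) >= 1, length(lon) >= 1)
  if (is.unsorted(lat, strictly = TRUE)) abort("lat must be strictly increasing")
  lon <- normalize_lon(lon)
  if (anyDuplicated(lon)) abort("duplicate longitudes after normalisation")
  if (is.null(ocean_mask)) {
    ocean_mask <- matrix(TRUE, length(lat), length(lon))
  }
  ocean_mask <- as.matrix(ocean_mask)
  if (!identical(dim(ocean_mask), c(length(lat), length(lon)))) {
    abort("ocean_mask must be a lat x lon logical matrix")
  }
  dlat <- cell_extent(lat)
  dlon <- cell_extent(lon[order(lon)])[order(order(lon))]
  w <- outer(cos(lat * pi / 180) * dlat, dlon)
  w[w < 0] <- 0  # guards poles at |lat| ~ 90
  w[!ocean_mask] <- 0
  if (!any(w > 0)) abort("grid has no ocean cell with positive area weight")
  structure(list(lat = lat, lon = lon, area_weight = w, ocean_mask = ocean_mask),
            class = "plankton_grid")
}

normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# Angular cell extent from centre spacing; regular spacing assumed at the ends.
cell_extent <- function(x) {
  if (length(x) == 1) return(1)
  d <- diff(x)
  mid <- c(x[1] - d[1] / 2, x[-length(x)] + d / 2, x[length(x)] + d[length(d)] / 2)
  diff(mid)
}

#' @export
print.plankton_grid <- function(x, ...) {
  cat(sprintf("<plankton_grid> %d lat x %d lon (%d ocean cells)\n",
              length(x$lat), length(x$lon), sum(x$ocean_mask)))
  invisible(x)
}

#' @describeIn make_grid Grid cells as a tibble (`lat`, `lon`, `area_weight`,
#'   `ocean`), one row per cell.
#' @param x A `plankton_grid`.
#' @param ... Unused.
#' @export
as_tibble.plankton_grid <- function(x, ...) {
  tibble::tibble(
    lat = rep(x$lat, times = length(x$lon)),
    lon = rep(x$lon, each = length(x$lat)),
    area_weight = as.vector(x$area_weight),
    ocean = as.vector(x$ocean_mask)
  )
}
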
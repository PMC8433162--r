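#' Gridded depth-integrated biomass field
#'
#' The central data container: a `time x lat x lon x type` array of
#' depth-integrated biomass (mass carbon per area), together with its grid and
#' type registry. Biomass is nonnegative on ocean cells and `NA` on land;
#' missing values are never silently turned into zeros.
#'
#' @param values Numeric array `[time, lat, lon, type]`, nonnegative on ocean.
#' @param years Integer vector of calendar years (annual means), one per time
#'   slice.
#' @param grid A [make_grid()] object.
#' @param registry A type registry, see [default_type_registry()].
#' @param units Biomass units string (default `"mgC m-2"`).
#' @param period Optional length-2 numeric `(start_year, end_year)` recording
#'   that the field is a period mean.
#'
#' @return An object of class `biomass_field`.
#' @export
biomass_field <- function(values, years, grid, registry,
                          units = "mgC m-2", period = NULL) {
  stopifnot(inherits(grid, "plankton_grid"))
  dims <- dim(values)
  if (length(dims) != 4) abort("values must be a 4-d array [time, lat, lon, type]")
  if (dims[1] != length(years)) abort("time dimension must match length(years)")
  if (dims[2] != length(grid$lat) || dims[3] != length(grid$lon)) {
    abort("spatial dimensions must match the grid")
  }
  if (dims[4] != nrow(registry)) {
    abort("type dimension length must equal the registry length")
  }
  # land cells carry NA throughout
  land <- !grid$ocean_mask
  if (any(land)) {
    la <- array(rep(land, each = dims[1]), dim = dims)
    values[la] <- NA_real_
  }
  ocean_vals <- values[!is.na(values)]
  if (any(ocean_vals < 0)) abort("biomass must be nonnegative on ocean cells")
  structure(
    list(values = values, years = as.integer(years), grid = grid,
         registry = registry, units = units, period = period),
    class = "biomass_field"
  )
}

#' @export
print.biomass_field <- function(x, ...) {
  cat(sprintf(
    "<biomass_field> %d year(s) %d-%d, %d x %d grid, %d types (%s)\n",
    length(x$years), min(x$years), max(x$years),
    length(x$grid$lat), length(x$grid$lon), nrow(x$registry), x$units))
  if (!is.null(x$period)) {
    cat(sprintf("  period mean %d-%d\n", x$period[1], x$period[2]))
  }
  invisible(x)
}

#' Collapse a biomass field to a period mean
#'
#' Arithmetic mean over the calendar years in the inclusive range
#' `[start_year, end_year]` (so 2005--2024 averages exactly 20 annual slices).
#' The result keeps a time dimension of length 1 and records the period.
#'
#' @param field A [biomass_field()].
#' @param start_year,end_year Inclusive calendar-year bounds.
#' @return A `biomass_field` with one time slice and `period` set.
#' @export
#' @examples
#' fld <- generate_parametric(parametric_scenario(n_types = 8, richness = 4),
#'                            make_grid(0, 0), years = 2005:2010, seed = 1)
#' period_mean(fld, 2005, 2008)
period_mean <- function(field, start_year, end_year) {
  stopifnot(inherits(field, "biomass_field"))
  if (end_year < start_year) abort("end_year must be >= start_year")
  keep <- field$years >= start_year & field$years <= end_year
  if (!any(keep)) {
    abort(sprintf("period %d-%d does not intersect field years %d-%d",
                  start_year, end_year, min(field$years), max(field$years)))
  }
  d <- dim(field$values)
  sub <- field$values[keep, , , , drop = FALSE]
  m <- colMeans(sub, dims = 1)              # lat x lon x type
  out <- array(m, dim = c(1, d[2], d[3], d[4]))
  biomass_field(out, years = start_year, grid = field$grid,
                registry = field$registry, units = field$units,
                period = c(start_year, end_year))
}

#' @describeIn biomass_field Long-format view: one row per
#'   year/cell/type with biomass (land rows carry `NA`).
#' @param x A `biomass_field`.
#' @param ... Unused.
#' @export
as_tibble.biomass_field <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    year = rep(x$years, times = prod(d[2:4])),
    lat = rep(rep(x$grid$lat, each = d[1]), times = d[3] * d[4]),
    lon = rep(rep(x$grid$lon, each = d[1] * d[2]), times = d[4]),
    type_id = rep(x$registry$type_id, each = prod(d[1:3])),
    group = rep(x$registry$group, each = prod(d[1:3])),
    biomass = as.vector(x$values)
  )
}

#' Total phytoplankton biomass per cell
#'
#' Sums biomass over phytoplankton types (zooplankton excluded), returning a
#' gridded metric. With multiple time slices the result carries a `year`
#' column.
#'
#' @param field A [biomass_field()].
#' @return A [metric_field] tibble with columns `lat`, `lon` (and `year` if
#'   time-resolved) and `value`.
#' @export
total_phyto_biomass <- function(field) {
  stopifnot(inherits(field, "biomass_field"))
  M <- phyto_matrix(field)                  # (time*lat*lon) x n_phyto
  tot <- rowSums(M)
  metric_from_cube(tot, field, metric_name = "total_phyto_biomass",
                   units = field$units)
}

# Reshape the phytoplankton slab to a (time*lat*lon) x n_phyto matrix.
phyto_matrix <- function(field) {
  d <- dim(field$values)
  ph <- which(field$registry$trophic_role == "phytoplankton")
  matrix(field$values[, , , ph, drop = FALSE], nrow = prod(d[1:3]),
         ncol = length(ph))
}
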
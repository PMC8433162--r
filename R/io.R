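#' netCDF layout description for biomass files
#'
#' Deposited model output does not follow one naming convention, so the reader
#' takes an explicit layout instead of guessing: the names of the four
#' dimensions and of the biomass and type-metadata variables.
#'
#' @param biomass_var Name of the biomass variable (`time x lat x lon x type`
#'   in any storage order; dimensions are matched by name).
#' @param time_dim,lat_dim,lon_dim,type_dim Dimension names.
#' @param esd_var Name of the per-type ESD variable (um).
#' @param group_attr Name of the global attribute holding the comma-separated
#'   per-type group labels.
#' @param size_class_var Name of the per-type phytoplankton size-class
#'   variable (NA/fill for zooplankton), or NULL to derive classes from ESD.
#' @return A `biomass_layout` list.
#' @export
biomass_layout <- function(biomass_var = "biomass", time_dim = "time",
                           lat_dim = "lat", lon_dim = "lon",
                           type_dim = "type", esd_var = "type_esd_um",
                           group_attr = "type_group",
                           size_class_var = "type_size_class") {
  structure(list(biomass_var = biomass_var, time_dim = time_dim,
                 lat_dim = lat_dim, lon_dim = lon_dim, type_dim = type_dim,
                 esd_var = esd_var, group_attr = group_attr,
                 size_class_var = size_class_var),
            class = "biomass_layout")
}

#' Write a biomass field to netCDF
#'
#' Classic-format (netCDF-3) file with dimensions `time`, `lat`, `lon`,
#' `type`, the biomass variable (units in its attributes), per-type ESD and
#' size-class variables, and group labels as a global attribute. Land cells
#' are stored as NaN. Classic format keeps repeated writes of the same field
#' byte-identical.
#'
#' @param field A [biomass_field()].
#' @param path Output path.
#' @param layout A [biomass_layout()] naming variables and dimensions.
#' @return `path`, invisibly.
#' @export
write_biomass <- function(field, path, layout = biomass_layout()) {
  stopifnot(inherits(field, "biomass_field"))
  d_time <- ncdf4::ncdim_def(layout$time_dim, "year", as.double(field$years))
  d_lat <- ncdf4::ncdim_def(layout$lat_dim, "degrees_north", field$grid$lat)
  d_lon <- ncdf4::ncdim_def(layout$lon_dim, "degrees_east", field$grid$lon)
  d_type <- ncdf4::ncdim_def(layout$type_dim, "",
                             as.double(field$registry$type_id))
  v_bio <- ncdf4::ncvar_def(layout$biomass_var, field$units,
                            list(d_time, d_lat, d_lon, d_type),
                            prec = "double")
  v_esd <- ncdf4::ncvar_def(layout$esd_var, "um", list(d_type),
                            prec = "double")
  v_cls <- ncdf4::ncvar_def(layout$size_class_var, "1", list(d_type),
                            missval = -1, prec = "integer")
  nc <- ncdf4::nc_create(path, list(v_bio, v_esd, v_cls), force_v4 = FALSE)
  on.exit(ncdf4::nc_close(nc))
  vals <- field$values
  vals[is.na(vals)] <- NaN
  ncdf4::ncvar_put(nc, v_bio, vals)
  ncdf4::ncvar_put(nc, v_esd, field$registry$esd_um)
  cls <- field$registry$size_class
  cls[is.na(cls)] <- -1L
  ncdf4::ncvar_put(nc, v_cls, cls)
  ncdf4::ncatt_put(nc, 0, layout$group_attr,
                   paste(field$registry$group, collapse = ","))
  ncdf4::ncatt_put(nc, 0, "type_name",
                   paste(field$registry$name, collapse = ","))
  ncdf4::ncatt_put(nc, 0, "type_trophic_role",
                   paste(field$registry$trophic_role, collapse = ","))
  if (!is.null(field$period)) {
    ncdf4::ncatt_put(nc, 0, "period_start", field$period[1], prec = "int")
    ncdf4::ncatt_put(nc, 0, "period_end", field$period[2], prec = "int")
  }
  invisible(path)
}

#' Read a biomass field from netCDF
#'
#' Validates the layout (a missing dimension or variable is a format error
#' naming the missing item), normalises 0--360 longitudes to `[-180, 180)`,
#' clamps tiny negative values to zero, and maps all-missing cells to land.
#' NaN at a cell that also holds finite biomass (a partially missing ocean
#' cell) is a validation error — missing values are never silently zeroed.
#'
#' @param path netCDF file path.
#' @param layout A [biomass_layout()].
#' @param neg_tol Negative values with magnitude below this are clamped to 0;
#'   anything more negative is a validation error.
#' @return A [biomass_field()].
#' @export
read_biomass <- function(path, layout = biomass_layout(), neg_tol = 1e-8) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  dims_present <- names(nc$dim)
  for (dn in c(layout$time_dim, layout$lat_dim, layout$lon_dim,
               layout$type_dim)) {
    if (!dn %in% dims_present) {
      abort(sprintf("format error: file lacks dimension '%s'", dn))
    }
  }
  if (!layout$biomass_var %in% names(nc$var)) {
    abort(sprintf("format error: file lacks variable '%s'",
                  layout$biomass_var))
  }
  v <- nc$var[[layout$biomass_var]]
  dim_names <- vapply(v$dim, function(d) d$name, character(1))
  want <- c(layout$time_dim, layout$lat_dim, layout$lon_dim, layout$type_dim)
  if (!setequal(dim_names, want)) {
    abort(sprintf("format error: variable '%s' has dims (%s), expected (%s)",
                  layout$biomass_var, paste(dim_names, collapse = ", "),
                  paste(want, collapse = ", ")))
  }
  vals <- ncdf4::ncvar_get(nc, layout$biomass_var, collapse_degen = FALSE)
  vals <- aperm(vals, match(want, dim_names))
  years <- as.integer(nc$dim[[layout$time_dim]]$vals)
  lat <- as.double(nc$dim[[layout$lat_dim]]$vals)
  lon_raw <- as.double(nc$dim[[layout$lon_dim]]$vals)
  lon <- normalize_lon(lon_raw)
  ord_lat <- order(lat)
  ord_lon <- order(lon)
  vals <- vals[, ord_lat, ord_lon, , drop = FALSE]
  lat <- lat[ord_lat]; lon <- lon[ord_lon]

  registry <- registry_from_nc(nc, layout)
  units <- ncdf4::ncatt_get(nc, layout$biomass_var, "units")$value
  if (!is.character(units)) units <- "unknown"

  # land = cells missing for every time/type; partial missingness is an error
  n_na <- apply(is.na(vals), c(2, 3), sum)
  n_tt <- dim(vals)[1] * dim(vals)[4]
  partial <- n_na > 0 & n_na < n_tt
  if (any(partial)) {
    abort(sprintf(
      "validation error: %d ocean cell(s) contain NaN alongside finite biomass",
      sum(partial)))
  }
  ocean <- n_na == 0
  neg <- !is.na(vals) & vals < 0
  if (any(!is.na(vals) & vals < -neg_tol)) {
    abort("validation error: biomass below -neg_tol; not clamping")
  }
  vals[neg] <- 0

  grid <- make_grid(lat, lon, ocean_mask = ocean)
  per <- NULL
  ps <- ncdf4::ncatt_get(nc, 0, "period_start")
  pe <- ncdf4::ncatt_get(nc, 0, "period_end")
  if (ps$hasatt && pe$hasatt) per <- c(ps$value, pe$value)
  biomass_field(vals, years, grid, registry, units = units, period = per)
}

registry_from_nc <- function(nc, layout) {
  if (!layout$esd_var %in% names(nc$var)) {
    abort(sprintf("format error: file lacks variable '%s'", layout$esd_var))
  }
  esd <- as.double(ncdf4::ncvar_get(nc, layout$esd_var))
  n <- length(esd)
  grp <- ncdf4::ncatt_get(nc, 0, layout$group_attr)
  groups <- if (grp$hasatt) strsplit(grp$value, ",")[[1]] else
    rep("diatom", n)
  role_att <- ncdf4::ncatt_get(nc, 0, "type_trophic_role")
  roles <- if (role_att$hasatt) strsplit(role_att$value, ",")[[1]] else
    ifelse(groups == "zooplankton", "zooplankton", "phytoplankton")
  name_att <- ncdf4::ncatt_get(nc, 0, "type_name")
  nms <- if (name_att$hasatt) strsplit(name_att$value, ",")[[1]] else
    sprintf("type_%02d", seq_len(n))
  cls <- rep(NA_integer_, n)
  if (!is.null(layout$size_class_var) &&
      layout$size_class_var %in% names(nc$var)) {
    cls <- as.integer(ncdf4::ncvar_get(nc, layout$size_class_var))
    cls[cls < 0] <- NA_integer_
  } else {
    ph <- roles == "phytoplankton"
    rng <- range(esd[ph])
    breaks <- exp(seq(log(rng[1]) - 1e-9, log(rng[2]) + 1e-9,
                      length.out = 17))
    cls[ph] <- as.integer(cut(esd[ph], breaks = breaks, labels = FALSE))
  }
  reg <- tibble::tibble(type_id = seq_len(n), name = nms, group = groups,
                        esd_um = esd, size_class = cls, trophic_role = roles)
  validate_registry(reg, allow_custom_counts = TRUE)
  reg
}

#' Write a gridded metric to netCDF
#'
#' Classic-format file with CF-style `lat`/`lon` (and `time`) coordinates,
#' the metric values (NaN for land/undefined cells, never zero-filled), and
#' metric name, units and period as global attributes.
#'
#' @param metric A [metric_field].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric <- function(metric, path) {
  stopifnot(inherits(metric, "metric_field"))
  g <- attr(metric, "grid")
  lat <- if (!is.null(g)) g$lat else sort(unique(metric$lat))
  lon <- if (!is.null(g)) g$lon else sort(unique(metric$lon))
  has_time <- "year" %in% names(metric)
  years <- if (has_time) sort(unique(metric$year)) else NULL
  d_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat)
  d_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon)
  dims <- list(d_lat, d_lon)
  if (has_time) {
    dims <- c(list(ncdf4::ncdim_def("time", "year", as.double(years))), dims)
  }
  name <- attr(metric, "metric_name")
  v <- ncdf4::ncvar_def(name, attr(metric, "units"), dims, prec = "double")
  nc <- ncdf4::nc_create(path, v, force_v4 = FALSE)
  on.exit(ncdf4::nc_close(nc))
  key_lat <- match(metric$lat, lat)
  key_lon <- match(metric$lon, lon)
  if (has_time) {
    arr <- array(NaN, dim = c(length(years), length(lat), length(lon)))
    arr[cbind(match(metric$year, years), key_lat, key_lon)] <- metric$value
  } else {
    arr <- array(NaN, dim = c(length(lat), length(lon)))
    arr[cbind(key_lat, key_lon)] <- metric$value
  }
  arr[is.na(arr)] <- NaN
  ncdf4::ncvar_put(nc, v, arr)
  ncdf4::ncatt_put(nc, 0, "metric_name", name)
  per <- attr(metric, "period")
  if (!is.null(per) && !is.list(per)) {
    ncdf4::ncatt_put(nc, 0, "period_start", per[1], prec = "int")
    ncdf4::ncatt_put(nc, 0, "period_end", per[2], prec = "int")
  }
  if (is.list(per)) {
    ncdf4::ncatt_put(nc, 0, "period",
                     paste(vapply(per, paste, character(1), collapse = "-"),
                           collapse = " vs "))
  }
  invisible(path)
}

#' Read a gridded metric written by [write_metric()]
#'
#' @param path netCDF file path.
#' @param var Variable name; default: the single non-coordinate variable.
#' @return A [metric_field]; NaN cells come back as `NA` values, preserved on
#'   their grid rows.
#' @export
read_metric <- function(path, var = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(var)) var <- names(nc$var)[1]
  vals <- ncdf4::ncvar_get(nc, var, collapse_degen = FALSE)
  vdims <- vapply(nc$var[[var]]$dim, function(d) d$name, character(1))
  lat <- as.double(nc$dim$lat$vals)
  lon <- as.double(nc$dim$lon$vals)
  has_time <- "time" %in% vdims
  vals <- aperm(vals, match(c(if (has_time) "time", "lat", "lon"), vdims))
  nla <- length(lat); nlo <- length(lon)
  if (has_time) {
    years <- as.double(nc$dim$time$vals)
    ny <- length(years)
    df <- tibble::tibble(
      year = rep(years, times = nla * nlo),
      lat = rep(rep(lat, each = ny), times = nlo),
      lon = rep(lon, each = ny * nla),
      value = as.vector(vals)
    )
  } else {
    df <- tibble::tibble(
      lat = rep(lat, times = nlo),
      lon = rep(lon, each = nla),
      value = as.vector(vals)
    )
  }
  df$value[is.nan(df$value)] <- NA_real_
  name <- ncdf4::ncatt_get(nc, 0, "metric_name")
  nm <- if (name$hasatt) name$value else var
  per <- NULL
  ps <- ncdf4::ncatt_get(nc, 0, "period_start")
  pe <- ncdf4::ncatt_get(nc, 0, "period_end")
  if (ps$hasatt && pe$hasatt) per <- c(ps$value, pe$value)
  units <- ncdf4::ncatt_get(nc, var, "units")$value
  metric_field(df, metric_name = nm,
               units = if (is.character(units)) units else "1", period = per)
}
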
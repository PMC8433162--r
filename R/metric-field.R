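#' Gridded metric result
#'
#' All diversity, turnover and spectrum operations return a `metric_field`: a
#' tibble with one row per grid cell (and per year, for time-resolved metrics)
#' holding the metric value, `NA` where the metric is undefined (land, or e.g.
#' evenness where richness <= 1). Metric name, units, grid and period metadata
#' travel as attributes so results can be written to netCDF and plotted.
#'
#' @param data A tibble with columns `lat`, `lon`, optionally `year`, and
#'   `value`.
#' @param metric_name Short metric identifier, e.g. `"richness"`.
#' @param units Units string (`"1"` for dimensionless).
#' @param grid The [make_grid()] object the metric lives on.
#' @param period Period metadata: length-2 numeric, or a list of two periods
#'   for difference metrics, or NULL.
#' @return A tibble of class `metric_field`.
#' @export
metric_field <- function(data, metric_name, units = "1", grid = NULL,
                         period = NULL) {
  stopifnot(all(c("lat", "lon", "value") %in% names(data)))
  structure(
    tibble::as_tibble(data),
    metric_name = metric_name, units = units, grid = grid, period = period,
    class = c("metric_field", class(tibble::tibble()))
  )
}

#' @export
print.metric_field <- function(x, ...) {
  p <- attr(x, "period")
  cat(sprintf("<metric_field> %s [%s]%s\n", attr(x, "metric_name"),
              attr(x, "units"), format_period(p)))
  NextMethod()
}

format_period <- function(p) {
  if (is.null(p)) return("")
  if (is.list(p)) {
    return(sprintf(" (%s vs %s)", paste(p[[1]], collapse = "-"),
                   paste(p[[2]], collapse = "-")))
  }
  sprintf(" (%d-%d)", p[1], p[2])
}

# Build a metric_field from a flat vector laid out as the field cube
# (time, lat, lon), dropping the year column for single-slice fields.
metric_from_cube <- function(v, field, metric_name, units = "1",
                             period = field$period) {
  d <- dim(field$values)
  df <- tibble::tibble(
    year = rep(field$years, times = d[2] * d[3]),
    lat = rep(rep(field$grid$lat, each = d[1]), times = d[3]),
    lon = rep(field$grid$lon, each = d[1] * d[2]),
    value = v
  )
  if (d[1] == 1) df$year <- NULL
  metric_field(df, metric_name = metric_name, units = units,
               grid = field$grid, period = period)
}

#' @describeIn metric_field Plain-tibble view of the values.
#' @param x A `metric_field`.
#' @param ... Unused.
#' @export
tidy.metric_field <- function(x, ...) {
  out <- tibble::as_tibble(unclass_metric(x))
  out$metric <- attr(x, "metric_name")
  out
}

unclass_metric <- function(x) {
  class(x) <- setdiff(class(x), "metric_field")
  x
}

#' @describeIn metric_field One-row summary: metric name, n cells defined,
#'   mean/min/max of the value.
#' @export
glance.metric_field <- function(x, ...) {
  tibble::tibble(
    metric = attr(x, "metric_name"),
    units = attr(x, "units"),
    n_defined = sum(!is.na(x$value)),
    n_missing = sum(is.na(x$value)),
    mean = mean(x$value, na.rm = TRUE),
    min = suppressWarnings(min(x$value, na.rm = TRUE)),
    max = suppressWarnings(max(x$value, na.rm = TRUE))
  )
}

#' @describeIn metric_field Quick-look map of a gridded metric
#'   (`ggplot2::geom_raster`), faceted by year when time-resolved.
#' @param object A `metric_field`.
#' @export
autoplot.metric_field <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(unclass_metric(object)),
                       ggplot2::aes(x = .data$lon, y = .data$lat,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = attr(object, "metric_name"),
                  title = sprintf("%s%s", attr(object, "metric_name"),
                                  format_period(attr(object, "period"))),
                  x = "longitude", y = "latitude")
  if ("year" %in% names(object)) p <- p + ggplot2::facet_wrap(~year)
  p
}
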
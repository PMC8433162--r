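#' Latitude-band region masks
#'
#' Builds the named ocean regions used for area-fraction reporting. A cell
#' belongs to a latitude band when its *centre* latitude lies in the half-open
#' interval `[south, north)`, so touching bands never double-count a row.
#' All band edges are configurable; the Southern Ocean boundary (45°S) and
#' the subtropics band (23°--40°, both hemispheres) are package defaults with
#' no canonical definition.
#'
#' @param grid A [make_grid()] object.
#' @param name One of `"global"`, `"band"` (use `south`/`north`),
#'   `"n_temperate"` (23°N--55°N), `"polar_or_equatorial"` (poleward of
#'   `polar_edge` in either hemisphere, or within `equator_edge` of the
#'   equator), `"subtropics"` (both hemispheres), `"southern_ocean"`.
#' @param south,north Band edges (degrees) for `name = "band"`.
#' @param polar_edge,equator_edge,subtropics_edges,southern_edge Configurable
#'   edges for the named regions.
#' @return A `region_mask` tibble: one row per grid cell with `lat`, `lon`,
#'   `area_weight`, `ocean`, `in_region`, plus a `region` attribute.
#' @export
region_mask <- function(grid,
                        name = c("global", "band", "n_temperate",
                                 "polar_or_equatorial", "subtropics",
                                 "southern_ocean"),
                        south = NULL, north = NULL,
                        polar_edge = 55, equator_edge = 23,
                        subtropics_edges = c(23, 40), southern_edge = -45) {
  name <- match.arg(name)
  cells <- as_tibble(grid)
  lat <- cells$lat
  in_band <- function(s, n) lat >= s & lat < n
  sel <- switch(name,
    global = rep(TRUE, nrow(cells)),
    band = {
      if (is.null(south) || is.null(north)) {
        abort("name = 'band' needs south and north edges")
      }
      in_band(south, north)
    },
    n_temperate = in_band(23, 55),
    polar_or_equatorial =
      lat >= polar_edge | lat < -polar_edge |
      (lat >= -equator_edge & lat < equator_edge),
    subtropics =
      in_band(subtropics_edges[1], subtropics_edges[2]) |
      in_band(-subtropics_edges[2], -subtropics_edges[1]),
    southern_ocean = lat < southern_edge
  )
  cells$in_region <- sel & cells$ocean
  structure(cells, region = name, class = c("region_mask", class(cells)))
}

#' Percent change between two period metrics
#'
#' `100 * (end - base) / base` per cell; undefined (`NA`) where the baseline
#' is zero or negative or either input is missing — never infinite.
#'
#' @param base,end [metric_field]s on the same grid (same cell ordering).
#' @return A [metric_field], percent.
#' @export
percent_change <- function(base, end) {
  if (nrow(base) != nrow(end) ||
      !isTRUE(all.equal(base$lat, end$lat)) ||
      !isTRUE(all.equal(base$lon, end$lon))) {
    abort("metrics must be on the same grid")
  }
  out <- base
  ok <- !is.na(base$value) & !is.na(end$value) & base$value > 0
  out$value <- ifelse(ok, 100 * (end$value - base$value) / base$value,
                      NA_real_)
  attr(out, "metric_name") <- paste0("pct_change_", attr(base, "metric_name"))
  attr(out, "units") <- "%"
  attr(out, "period") <- list(attr(base, "period"), attr(end, "period"))
  out
}

#' Area-weighted fraction of a region meeting a condition
#'
#' Fraction of the region's ocean area where a metric satisfies a condition,
#' weighted by cosine-latitude cell area. "decline" and "increase" are strict
#' (`< 0`, `> 0`); exact zeros count as neither. Cells where the metric is
#' undefined are excluded from both numerator and denominator.
#'
#' @param metric A [metric_field] (single time slice) on the region's grid.
#' @param region A [region_mask()].
#' @param condition `"decline"`, `"increase"`, `"below"`, or `"above"`.
#' @param value Cut point for `"below"`/`"above"`.
#' @return A one-row tibble: `region`, `condition`, `fraction`,
#'   `n_cells_valid`.
#' @export
area_fraction <- function(metric,
                          condition = c("decline", "increase", "below", "above"),
                          region = NULL, value = NULL) {
  condition <- match.arg(condition)
  if (is.null(region)) {
    g <- attr(metric, "grid")
    if (is.null(g)) abort("metric carries no grid; supply a region mask")
    region <- region_mask(g, "global")
  }
  if (nrow(metric) != nrow(region) ||
      !isTRUE(all.equal(metric$lat, region$lat)) ||
      !isTRUE(all.equal(metric$lon, region$lon))) {
    abort("metric and region must be on the same grid")
  }
  v <- metric$value
  valid <- region$in_region & !is.na(v) & region$area_weight > 0
  if (!any(valid)) abort("no valid cells in the region")
  meets <- switch(condition,
    decline = v < 0,
    increase = v > 0,
    below = { if (is.null(value)) abort("'below' needs a value"); v < value },
    above = { if (is.null(value)) abort("'above' needs a value"); v > value }
  )
  w <- region$area_weight
  frac <- sum(w[valid & meets], na.rm = TRUE) / sum(w[valid])
  tibble::tibble(
    metric = attr(metric, "metric_name"),
    region = attr(region, "region"),
    condition = if (condition %in% c("below", "above")) {
      sprintf("%s %g", condition, value)
    } else condition,
    fraction = frac,
    n_cells_valid = sum(valid)
  )
}

#' Default regional summary configuration
#'
#' One row per (metric, region, condition) evaluated by [summary_report()]:
#' percent change in total biomass, richness and evenness, change in Shannon
#' index, change in turnover rate, and change in size-spectrum slope, each as
#' decline/increase fractions over the standard regions.
#'
#' @return A tibble with columns `metric`, `region`, `condition`.
#' @export
default_report_config <- function() {
  tibble::tribble(
    ~metric,                 ~region,                ~condition,
    "total_phyto_biomass",   "global",               "decline",
    "total_phyto_biomass",   "global",               "increase",
    "richness",              "n_temperate",          "decline",
    "richness",              "polar_or_equatorial",  "increase",
    "shannon",               "global",               "decline",
    "evenness",              "global",               "decline",
    "turnover_rate_change",  "global",               "increase",
    "size_spectrum_slope",   "subtropics",           "decline",
    "size_spectrum_slope",   "southern_ocean",       "decline",
    "size_spectrum_slope",   "global",               "increase"
  )
}

#' Regional area-fraction summary report
#'
#' Runs the full pipeline on one biomass field — period means, percent-change
#' (biomass, richness, evenness) or difference (Shannon, size-spectrum slope,
#' turnover rate) fields between a baseline and an end-of-run period — and
#' tabulates the area-weighted fraction of each configured region meeting each
#' condition. Deterministic for a given field and config.
#'
#' @param field A [biomass_field()] spanning both periods.
#' @param config A tibble as [default_report_config()].
#' @param base_period,end_period Inclusive year ranges for the comparison.
#' @param threshold_fraction Presence threshold, default `0.001`.
#' @param early_pair,late_pair Period pairs for the turnover-rate-change row,
#'   see [turnover_rate_change()].
#' @param csv_path Optional path: the table is also written as CSV.
#' @param nc_dir Optional directory: each underlying change field is written
#'   as `<metric>.nc`.
#' @return A tibble of [area_fraction()] rows.
#' @export
summary_report <- function(field, config = default_report_config(),
                           base_period = c(2005, 2024),
                           end_period = c(2081, 2100),
                           threshold_fraction = 0.001,
                           early_pair = list(c(2011, 2030), c(2031, 2040)),
                           late_pair = list(c(2061, 2080), c(2081, 2100)),
                           csv_path = NULL, nc_dir = NULL) {
  ch <- change_fields(field, base_period, end_period, threshold_fraction,
                      metrics = unique(config$metric),
                      early_pair = early_pair, late_pair = late_pair)
  rows <- purrr::pmap_dfr(config, function(metric, region, condition) {
    m <- ch[[metric]]
    if (is.null(m)) abort(sprintf("unknown metric '%s' in config", metric))
    rm <- region_mask(field$grid, region)
    area_fraction(m, condition = condition, region = rm)
  })
  if (!is.null(csv_path)) readr::write_csv(rows, csv_path)
  if (!is.null(nc_dir)) {
    if (!dir.exists(nc_dir)) dir.create(nc_dir, recursive = TRUE)
    for (m in ch) {
      write_metric(m, file.path(nc_dir, paste0(attr(m, "metric_name"), ".nc")))
    }
  }
  rows
}

# The comparison fields behind the report, one metric_field per metric name.
change_fields <- function(field, base_period, end_period, threshold_fraction,
                          metrics,
                          early_pair = list(c(2011, 2030), c(2031, 2040)),
                          late_pair = list(c(2061, 2080), c(2081, 2100))) {
  base <- period_mean(field, base_period[1], base_period[2])
  end <- period_mean(field, end_period[1], end_period[2])
  out <- list()
  need <- function(m) m %in% metrics
  if (need("total_phyto_biomass")) {
    out$total_phyto_biomass <-
      percent_change(total_phyto_biomass(base), total_phyto_biomass(end))
  }
  if (need("richness")) {
    out$richness <- percent_change(richness(base, threshold_fraction),
                                   richness(end, threshold_fraction))
  }
  if (need("evenness")) {
    out$evenness <- percent_change(evenness(base, threshold_fraction),
                                   evenness(end, threshold_fraction))
  }
  if (need("shannon")) {
    sb <- shannon(base, threshold_fraction)
    se <- shannon(end, threshold_fraction)
    d <- sb
    d$value <- se$value - sb$value
    attr(d, "metric_name") <- "shannon"
    out$shannon <- d
  }
  if (need("turnover_rate_change")) {
    out$turnover_rate_change <-
      turnover_rate_change(field, early_pair = early_pair,
                           late_pair = late_pair,
                           threshold_fraction = threshold_fraction)
  }
  if (need("size_spectrum_slope")) {
    sb <- spectrum_slope(base)
    se <- spectrum_slope(end)
    d <- sb
    d$value <- se$value - sb$value
    attr(d, "metric_name") <- "size_spectrum_slope"
    out$size_spectrum_slope <- d
  }
  out
}
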
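#' Assemble a global biomass field from per-latitude-band scenarios
#'
#' Each latitude band carries either a [parametric_scenario()] (cells drawn
#' independently) or a [sim_scenario()] (one deterministic community run per
#' band, broadcast to the band's cells), with mean-one multiplicative
#' lognormal noise per cell/year/type on top. Every ocean cell must fall in
#' some band. Deterministic given `seed`: bands are processed in list order,
#' noise is drawn after all scenario draws.
#'
#' @param scenarios List of bands; each element is a list with `lat_min`,
#'   `lat_max` (cell-centre latitudes in `[lat_min, lat_max)`) and
#'   `scenario`. The first matching band wins.
#' @param grid A [make_grid()] object.
#' @param years Integer vector of calendar years (ignored for sim scenarios,
#'   which carry their own years — these must match).
#' @param seed Integer seed for all randomness.
#' @param noise_sigma Standard deviation of log-noise (default 0.1); 0
#'   disables noise.
#' @param carbon_scale Factor converting the simulator's nitrogen currency to
#'   depth-integrated carbon (default 3980 mgC m-2 per mmol N m-3, i.e.
#'   Redfield C:N at 50 m effective depth).
#' @return A [biomass_field()].
#' @export
generate_world <- function(scenarios, grid, years = 2005:2100, seed = 1,
                           noise_sigma = 0.1, carbon_scale = 3980) {
  stopifnot(inherits(grid, "plankton_grid"))
  nlat <- length(grid$lat); nlon <- length(grid$lon); ny <- length(years)

  band_of <- rep(NA_integer_, nlat)
  for (b in seq_along(scenarios)) {
    sel <- grid$lat >= scenarios[[b]]$lat_min & grid$lat < scenarios[[b]]$lat_max
    band_of[is.na(band_of) & sel] <- b
  }
  uncovered <- which(is.na(band_of) & apply(grid$ocean_mask, 1, any))
  if (length(uncovered) > 0) {
    abort(sprintf("configuration error: ocean cells at latitude(s) %s have no scenario",
                  paste(round(grid$lat[uncovered], 1), collapse = ", ")))
  }

  registry <- NULL
  vals <- NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (b in seq_along(scenarios)) {
    rows <- which(band_of == b)
    if (length(rows) == 0) next
    sc <- scenarios[[b]]$scenario
    if (inherits(sc, "sim_scenario")) {
      if (!identical(sc$years, as.integer(years))) {
        abort("sim scenario years must match the field years")
      }
      reg <- sc$registry
      sim <- simulate_cell(sc)
      cell <- cbind(sim$phyto, sim$zoo) * carbon_scale   # years x types
      if (is.null(vals)) {
        registry <- reg
        vals <- array(NA_real_, dim = c(ny, nlat, nlon, nrow(reg)))
      }
      if (nrow(reg) != dim(vals)[4]) {
        abort("all bands must share one registry size")
      }
      for (i in rows) for (j in seq_len(nlon)) {
        if (grid$ocean_mask[i, j]) vals[, i, j, ] <- cell
      }
    } else if (inherits(sc, "parametric_scenario")) {
      sub_mask <- grid$ocean_mask[rows, , drop = FALSE]
      sub_grid <- make_grid(grid$lat[rows], grid$lon, ocean_mask = sub_mask)
      band_seed <- sample.int(.Machine$integer.max - 1, 1)
      f <- generate_parametric(sc, sub_grid, years, seed = band_seed)
      if (is.null(vals)) {
        registry <- f$registry
        vals <- array(NA_real_, dim = c(ny, nlat, nlon, nrow(f$registry)))
      }
      if (nrow(f$registry) != dim(vals)[4]) {
        abort("all bands must share one registry size")
      }
      vals[, rows, , ] <- f$values
    } else {
      abort("each band scenario must be a sim_scenario or parametric_scenario")
    }
  }
  # generate_parametric reseeds; restore a seed stream keyed to `seed` for noise
  set.seed(as.integer((seed + 7919) %% .Machine$integer.max))
  if (noise_sigma > 0) {
    noise <- exp(stats::rnorm(length(vals), mean = -noise_sigma^2 / 2,
                              sd = noise_sigma))
    vals <- vals * noise
  }
  biomass_field(vals, years, grid, registry, units = "mgC m-2")
}

#' Built-in synthetic presets
#'
#' `tiny`: a 4 x 4 all-ocean grid, 8 phytoplankton types, 10 years, from a
#' parametric scenario — fast enough for examples and round-trip tests.
#'
#' `century`: a coarse global grid shaped like a 2 deg x 2.5 deg world
#' (20 x 36 cells at 8 deg x 10 deg), the full 51-type registry, annual
#' fields 2005--2100, built from mechanistic per-band scenarios emulating a
#' high-emissions century: nutrient supply declining at low latitudes
#' (strongest in the tropics), supply rising and waters warming poleward —
#' so total phytoplankton biomass falls at low latitudes and rises at high
#' latitudes, and the tropical community shifts toward small types.
#'
#' @param name `"tiny"` or `"century"`.
#' @param seed Integer seed.
#' @param noise_sigma Lognormal noise level (default 0.1).
#' @return A [biomass_field()].
#' @export
preset_field <- function(name = c("tiny", "century"), seed = 1,
                         noise_sigma = 0.1) {
  name <- match.arg(name)
  if (name == "tiny") {
    grid <- make_grid(lat = c(-30, -10, 10, 30), lon = c(-135, -45, 45, 135))
    sc <- parametric_scenario(n_types = 8, richness = 5, evenness = 0.8,
                              turnover_per_step = 0.1)
    return(generate_world(list(list(lat_min = -90, lat_max = 90,
                                    scenario = sc)),
                          grid, years = 2005:2014, seed = seed,
                          noise_sigma = noise_sigma))
  }
  grid <- century_grid()
  generate_world(climate_scenarios(), grid, years = 2005:2100, seed = seed,
                 noise_sigma = noise_sigma)
}

#' @describeIn preset_field The coarse global grid used by `century`.
#' @export
century_grid <- function() {
  make_grid(lat = seq(-76, 76, by = 8), lon = seq(-175, 175, by = 10))
}

#' @describeIn preset_field The per-band climate-change emulation scenarios
#'   behind `century`: tropical and subtropical nutrient-supply decline,
#'   high-latitude supply increase and warming, all over 2005--2100.
#' @param years Years for the band scenarios.
#' @export
climate_scenarios <- function(years = 2005:2100) {
  ny <- length(years)
  ramp <- function(a, b) seq(a, b, length.out = ny)
  band <- function(lat_min, lat_max, S0, S1, T0, T1) {
    list(lat_min = lat_min, lat_max = lat_max,
         scenario = sim_scenario(years = years,
                                 nutrient_supply = ramp(S0, S1),
                                 temperature = ramp(T0, T1)))
  }
  list(
    band(-23, 23, 0.020, 0.013, 26, 29.5),   # tropics: strong supply decline
    band(23, 45, 0.025, 0.016, 20, 23),      # N subtropics
    band(-45, -23, 0.025, 0.016, 20, 23),    # S subtropics
    band(45, 66, 0.040, 0.038, 8, 11),       # N temperate/subpolar
    band(-66, -45, 0.040, 0.038, 8, 11),     # Southern Ocean fringe
    band(66, 90, 0.030, 0.039, 0, 3.5),      # Arctic: supply up, warming
    band(-90, -66, 0.030, 0.039, 0, 3.5)     # Antarctic
  )
}
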
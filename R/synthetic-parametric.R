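#' Parametric synthetic-community scenario
#'
#' Describes a community with *known* diversity structure, used to test the
#' metric pipeline against its own targets: a prescribed thresholded richness
#' (exact), a prescribed evenness (met to 1e-6 through a one-parameter
#' geometric family of biomass shares), a per-step replacement fraction of
#' the present types (presence turnover), and a multiplicative total-biomass
#' trend. `richness`, `evenness` and `total_biomass_trend` may be scalars or
#' per-year vectors.
#'
#' @param n_types Number of phytoplankton types in the pool.
#' @param richness Target thresholded richness (scalar or per-year).
#' @param evenness Target evenness in (0, 1] (scalar or per-year).
#' @param turnover_per_step Fraction of present types replaced each year, in
#'   `[0, 1]`; `ceiling(turnover_per_step * richness)` types are swapped.
#' @param total_biomass Baseline total biomass per cell.
#' @param total_biomass_trend Multiplicative factor on the total (scalar or
#'   per-year).
#' @param threshold_fraction Presence threshold the richness target is
#'   guaranteed against; the smallest generated share must stay at or above
#'   it, else the richness/evenness combination is rejected as unachievable.
#' @return A `parametric_scenario` list.
#' @export
parametric_scenario <- function(n_types = 35, richness = 10, evenness = 0.8,
                                turnover_per_step = 0, total_biomass = 1000,
                                total_biomass_trend = 1,
                                threshold_fraction = 0.001) {
  if (any(turnover_per_step < 0 | turnover_per_step > 1)) {
    abort("turnover_per_step must be in [0, 1]")
  }
  if (any(evenness <= 0 | evenness > 1)) abort("evenness must be in (0, 1]")
  if (any(richness < 1 | richness > n_types)) {
    abort("richness must be in 1..n_types")
  }
  structure(list(n_types = n_types, richness = richness, evenness = evenness,
                 turnover_per_step = turnover_per_step,
                 total_biomass = total_biomass,
                 total_biomass_trend = total_biomass_trend,
                 threshold_fraction = threshold_fraction),
            class = "parametric_scenario")
}

#' Geometric biomass shares with a prescribed evenness
#'
#' Solves the one-parameter geometric family `p_i` proportional to `q^(i-1)`
#' for the decay `q` in (0, 1] whose Shannon evenness equals the target
#' (within 1e-6 or better; evenness 1 gives equal shares). Errors when the
#' required smallest share would fall below the presence threshold, which
#' would break the exact-richness guarantee.
#'
#' @param s Number of types (richness), >= 1.
#' @param evenness Target evenness in (0, 1].
#' @param threshold_fraction Presence threshold to respect.
#' @return Numeric vector of `s` shares summing to 1, decreasing.
#' @export
geometric_shares <- function(s, evenness, threshold_fraction = 0.001) {
  if (s == 1) return(1)
  if (evenness >= 1) return(rep(1 / s, s))
  ev_of_q <- function(q) {
    p <- q^(0:(s - 1))
    p <- p / sum(p)
    -sum(p * log(p)) / log(s)
  }
  # evenness is increasing in q on (0, 1); bracket then root-find
  lo <- 1e-12
  if (ev_of_q(lo) > evenness) {
    abort("parameter error: evenness target below the geometric family's range")
  }
  q <- uniroot(function(q) ev_of_q(q) - evenness, c(lo, 1 - 1e-12),
               tol = 1e-14)$root
  p <- q^(0:(s - 1))
  p <- p / sum(p)
  if (min(p) < threshold_fraction) {
    abort(sprintf(
      paste0("parameter error: unachievable evenness/richness combination ",
             "(smallest share %.2e is below the %.2g presence threshold)"),
      min(p), threshold_fraction))
  }
  p
}

#' Generate a biomass field with known diversity structure
#'
#' Every ocean cell is populated independently: an initial random set of
#' `richness` present types, geometric shares meeting the evenness target
#' exactly, then per year a replacement of `ceiling(turnover_per_step *
#' richness)` present types by absent ones. Shares are shuffled over the
#' present set each year. Absent types hold zero biomass, so the pipeline's
#' thresholded richness equals the target exactly. Deterministic given
#' `seed`; draws occur cell-by-cell (column-major lat, then lon), year by
#' year within a cell.
#'
#' @param scenario A [parametric_scenario()].
#' @param grid A [make_grid()] object.
#' @param years Integer vector of calendar years.
#' @param seed Integer seed.
#' @return A [biomass_field()]. With `n_types = 35` the default registry is
#'   attached (zooplankton carried with zero biomass); otherwise a
#'   [toy_registry()].
#' @export
generate_parametric <- function(scenario, grid, years, seed = 1) {
  stopifnot(inherits(scenario, "parametric_scenario"),
            inherits(grid, "plankton_grid"))
  ny <- length(years)
  rep_y <- function(x) if (length(x) == 1) rep(x, ny) else
    if (length(x) == ny) x else
      abort("per-year scenario fields must be scalar or length(years)")
  s_t <- as.integer(rep_y(scenario$richness))
  e_t <- rep_y(scenario$evenness)
  f_t <- rep_y(scenario$turnover_per_step)
  m_t <- rep_y(scenario$total_biomass_trend)
  n <- scenario$n_types

  registry <- if (n == 35) default_type_registry() else toy_registry(n)
  n_all <- nrow(registry)
  phyto_idx <- which(registry$trophic_role == "phytoplankton")

  # pre-solve the share family for each distinct (richness, evenness) pair
  combos <- unique(data.frame(s = s_t, e = e_t))
  share_tab <- purrr::pmap(combos, function(s, e) {
    geometric_shares(s, e, scenario$threshold_fraction)
  })
  share_of <- function(t) {
    share_tab[[which(combos$s == s_t[t] & combos$e == e_t[t])[1]]]
  }

  nlat <- length(grid$lat); nlon <- length(grid$lon)
  vals <- array(NA_real_, dim = c(ny, nlat, nlon, n_all))
  set.seed(as.integer(seed %% .Machine$integer.max))
  resample <- function(x, k) x[sample.int(length(x), k)]

  for (j in seq_len(nlon)) {
    for (i in seq_len(nlat)) {
      if (!grid$ocean_mask[i, j]) next
      present <- resample(seq_len(n), s_t[1])
      for (t in seq_len(ny)) {
        s <- s_t[t]
        # adjust the set size toward the year's target
        while (length(present) < s) {
          present <- c(present, resample(setdiff(seq_len(n), present), 1))
        }
        if (length(present) > s) {
          present <- resample(present, s)
        }
        if (t > 1 && f_t[t] > 0) {
          k <- min(ceiling(f_t[t] * s), n - s, s)
          if (k > 0) {
            lost <- resample(present, k)
            gained <- resample(setdiff(seq_len(n), present), k)
            present <- c(setdiff(present, lost), gained)
          }
        }
        shares <- share_of(t)
        slot <- resample(present, s)   # shuffle shares over the set
        b <- numeric(n)
        b[slot] <- shares * scenario$total_biomass * m_t[t]
        vals[t, i, j, phyto_idx] <- b
        if (n_all > n) vals[t, i, j, -phyto_idx] <- 0
      }
    }
  }
  biomass_field(vals, years, grid, registry, units = "mgC m-2")
}
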
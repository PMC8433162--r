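# Independent oracles, written against the definitions rather than the
# package internals. Deliberately naive (loops, set operations).

# Shannon/evenness/richness of one biomass vector: threshold on share of the
# total, renormalise over included types, -sum p log p.
oracle_diversity <- function(biomass, threshold = 0.001) {
  tot <- sum(biomass)
  if (tot == 0) return(list(richness = 0, shannon = 0, evenness = NA_real_))
  share <- biomass / tot
  inc <- which(share >= threshold & share > 0)
  s <- length(inc)
  if (s <= 1) return(list(richness = s, shannon = 0, evenness = NA_real_))
  p <- biomass[inc] / sum(biomass[inc])
  H <- 0
  for (pi in p) H <- H - pi * log(pi)
  list(richness = s, shannon = H, evenness = H / log(s))
}

# Turnover by explicit set operations (Jaccard distance).
oracle_turnover <- function(setA, setB) {
  u <- union(setA, setB)
  if (length(u) == 0) return(NA_real_)
  (length(setdiff(setA, setB)) + length(setdiff(setB, setA))) / length(u)
}

# Theil-Sen by double loop over all pairs.
oracle_theil_sen <- function(x, y) {
  slopes <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j > i && x[j] != x[i]) {
        slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
      }
    }
  }
  median(slopes)
}

# Single-cell biomass field from a per-type x per-year biomass matrix.
# `mat`: n_years x n_types; registry defaults to a toy all-phyto registry.
cell_field <- function(mat, years = seq_len(nrow(mat)), registry = NULL) {
  if (is.null(registry)) registry <- toy_registry(ncol(mat))
  g <- make_grid(lat = 0, lon = 0)
  vals <- array(NA_real_, dim = c(nrow(mat), 1, 1, nrow(registry)))
  vals[, 1, 1, seq_len(ncol(mat))] <- mat
  if (nrow(registry) > ncol(mat)) {
    vals[, 1, 1, (ncol(mat) + 1):nrow(registry)] <- 0
  }
  biomass_field(vals, years, g, registry)
}

# Biomass field on an arbitrary grid from a function(cell_index) -> matrix.
grid_field <- function(grid, n_types, years, fill) {
  registry <- toy_registry(n_types)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  vals <- array(NA_real_, dim = c(length(years), nlat, nlon, n_types))
  k <- 0
  for (j in seq_len(nlon)) for (i in seq_len(nlat)) {
    k <- k + 1
    if (grid$ocean_mask[i, j]) vals[, i, j, ] <- fill(k)
  }
  biomass_field(vals, years, grid, registry)
}
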
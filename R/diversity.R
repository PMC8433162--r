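#' Thresholded phytoplankton presence
#'
#' A phytoplankton type counts as present at a cell/timestep when its share of
#' the total *phytoplankton* biomass there is at least `threshold_fraction`
#' (default 0.1%); rarer types are excluded from all diversity metrics.
#' Zooplankton never enter phytoplankton presence. Cells with zero total
#' phytoplankton biomass have no types present; land cells are `NA`.
#'
#' The share-equal-to-threshold boundary counts as present, applied uniformly
#' to presence, appearance and disappearance.
#'
#' @param field A [biomass_field()].
#' @param threshold_fraction Share threshold in `[0, 1)`, default `0.001`.
#' @return A `presence_field`: logical array `[time, lat, lon, n_phyto]` plus
#'   grid/registry metadata.
#' @export
presence <- function(field, threshold_fraction = 0.001) {
  stopifnot(inherits(field, "biomass_field"))
  if (!is.numeric(threshold_fraction) || threshold_fraction < 0 ||
      threshold_fraction >= 1) {
    abort("threshold_fraction must be in [0, 1)")
  }
  sh <- phyto_shares(field)
  pres <- !is.na(sh$share) & sh$share >= threshold_fraction & sh$share > 0
  pres[is.na(sh$share)] <- NA
  d <- dim(field$values)
  ph <- which(field$registry$trophic_role == "phytoplankton")
  structure(
    list(values = array(pres, dim = c(d[1:3], length(ph))),
         years = field$years, grid = field$grid,
         registry = field$registry[ph, , drop = FALSE],
         threshold_fraction = threshold_fraction, period = field$period),
    class = "presence_field"
  )
}

#' @export
print.presence_field <- function(x, ...) {
  cat(sprintf("<presence_field> threshold %.4g, %d year(s), %d phyto types\n",
              x$threshold_fraction, length(x$years), nrow(x$registry)))
  invisible(x)
}

# Biomass shares of total phytoplankton biomass, as a (time*lat*lon) x n_phyto
# matrix; rows with zero total get share 0, land rows NA.
phyto_shares <- function(field) {
  M <- phyto_matrix(field)
  tot <- rowSums(M)
  share <- M / tot
  zero <- !is.na(tot) & tot == 0
  share[zero, ] <- 0
  list(share = share, total = tot, biomass = M)
}

#' Functional richness
#'
#' Number of phytoplankton types coexisting above the presence threshold at
#' each cell (and timestep). An all-zero ocean cell has richness 0; land is
#' `NA`.
#'
#' @param x A `presence_field` from [presence()], or a [biomass_field()]
#'   (thresholded internally).
#' @param threshold_fraction Share threshold when `x` is a biomass field.
#' @param ... Unused.
#' @return A [metric_field] of integer counts.
#' @export
richness <- function(x, ...) UseMethod("richness")

#' @rdname richness
#' @export
richness.biomass_field <- function(x, threshold_fraction = 0.001, ...) {
  richness(presence(x, threshold_fraction))
}

#' @rdname richness
#' @export
richness.presence_field <- function(x, ...) {
  d <- dim(x$values)
  M <- matrix(x$values, nrow = prod(d[1:3]), ncol = d[4])
  s <- rowSums(M)
  fake <- list(values = x$values, years = x$years, grid = x$grid,
               period = x$period)
  metric_from_cube(s, fake, metric_name = "richness", units = "count",
                   period = x$period)
}

#' Shannon diversity index
#'
#' `-sum(p_i * ln(p_i))` over the biomass shares `p_i` of the types above the
#' presence threshold, with shares renormalised over the included types so
#' they sum to one. Reported in nats; 0 where at most one type is present.
#'
#' @inheritParams presence
#' @return A [metric_field], nats.
#' @export
shannon <- function(field, threshold_fraction = 0.001) {
  div <- diversity_components(field, threshold_fraction)
  metric_from_cube(div$shannon, field, metric_name = "shannon",
                   units = "nats")
}

#' Evenness
#'
#' Shannon index divided by the log of richness, in `[0, 1]`; equals 1 when
#' all included types hold equal biomass. Undefined (`NA`) where richness
#' <= 1, since `ln(1) = 0`.
#'
#' @inheritParams presence
#' @return A [metric_field], dimensionless.
#' @export
evenness <- function(field, threshold_fraction = 0.001) {
  div <- diversity_components(field, threshold_fraction)
  ev <- ifelse(div$richness >= 2, div$shannon / log(div$richness), NA_real_)
  metric_from_cube(ev, field, metric_name = "evenness", units = "1")
}

# Shared core: richness + Shannon per cell row.
diversity_components <- function(field, threshold_fraction = 0.001) {
  stopifnot(inherits(field, "biomass_field"))
  sh <- phyto_shares(field)
  inc <- sh$share >= threshold_fraction & sh$share > 0
  inc[is.na(sh$share)] <- FALSE
  p <- sh$share
  p[!inc] <- 0
  denom <- rowSums(p)
  s <- rowSums(inc)
  p <- p / ifelse(denom > 0, denom, 1)      # renormalise over included types
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  H <- -rowSums(plogp)
  H[s <= 1] <- 0
  H[is.na(sh$total)] <- NA_real_
  s <- ifelse(is.na(sh$total), NA_real_, s)
  list(richness = s, shannon = H)
}

#' Appearance and disappearance of types within a functional group
#'
#' Compares presence in two period-mean fields. A type *appears* at a cell
#' when its biomass share is below the threshold in the baseline period mean
#' and at/above it in the end period mean; *disappearance* is the reverse.
#' Counts are per functional group and bounded by the group size.
#'
#' @param base,end Period-mean [biomass_field()]s sharing grid and registry
#'   (see [period_mean()]).
#' @param group A phytoplankton group label, e.g. `"diatom"`.
#' @param threshold_fraction Share threshold, default `0.001`.
#' @return A named list of two [metric_field]s, `appearance` and
#'   `disappearance`.
#' @export
appearance_disappearance <- function(base, end, group,
                                     threshold_fraction = 0.001) {
  check_same_frame(base, end)
  if (!group %in% phyto_groups) {
    abort(sprintf("unknown phytoplankton group '%s'", group))
  }
  pb <- presence(base, threshold_fraction)
  pe <- presence(end, threshold_fraction)
  members <- which(pb$registry$group == group)
  db <- dim(pb$values)
  B <- matrix(pb$values[, , , members, drop = FALSE], nrow = prod(db[1:3]))
  E <- matrix(pe$values[, , , members, drop = FALSE], nrow = prod(db[1:3]))
  app <- rowSums(!B & E)
  dis <- rowSums(B & !E)
  app[rowSums(is.na(B) | is.na(E)) > 0] <- NA_real_
  dis[is.na(app)] <- NA_real_
  per <- list(base$period %||% range(base$years),
              end$period %||% range(end$years))
  list(
    appearance = metric_from_cube(app, base,
      metric_name = paste0("appearance_", group), units = "count",
      period = per),
    disappearance = metric_from_cube(dis, base,
      metric_name = paste0("disappearance_", group), units = "count",
      period = per)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_same_frame <- function(a, b) {
  if (!identical(a$registry$type_id, b$registry$type_id) ||
      !identical(a$registry$group, b$registry$group)) {
    abort("fields must share the same type registry")
  }
  if (!isTRUE(all.equal(a$grid$lat, b$grid$lat)) ||
      !isTRUE(all.equal(a$grid$lon, b$grid$lon))) {
    abort("fields must share the same grid")
  }
  invisible(TRUE)
}
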
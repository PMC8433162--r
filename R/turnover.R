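#' Community turnover between two timepoints
#'
#' Presence-based turnover `(N_G + N_L) / N_T`, where `N_G` is the number of
#' phytoplankton types gained, `N_L` the number lost, and `N_T` the total
#' number of types observed across both timepoints (the union of the two
#' presence sets — the only reading under which the metric stays in
#' `[0, 1]`). 0 means all types persist; 1 means all types change. Cells
#' where both presence sets are empty are undefined (`NA`), as is land. This
#' is the Jaccard distance between presence sets.
#'
#' Presence should be computed from *period-mean* biomass (see
#' [period_mean()] and [presence()]); [community_turnover()] wraps the whole
#' chain.
#'
#' @param base_presence,end_presence Single-timestep `presence_field`s sharing
#'   grid and registry.
#' @return A [metric_field] in `[0, 1]`.
#' @export
turnover <- function(base_presence, end_presence) {
  stopifnot(inherits(base_presence, "presence_field"),
            inherits(end_presence, "presence_field"))
  check_same_frame(base_presence, end_presence)
  db <- dim(base_presence$values)
  de <- dim(end_presence$values)
  if (db[1] != 1 || de[1] != 1) {
    abort("turnover expects single-timestep presence fields (period means)")
  }
  B <- matrix(base_presence$values, nrow = prod(db[1:3]), ncol = db[4])
  E <- matrix(end_presence$values, nrow = prod(de[1:3]), ncol = de[4])
  n_gain <- rowSums(!B & E)
  n_loss <- rowSums(B & !E)
  n_union <- rowSums(B | E)
  t <- ifelse(!is.na(n_union) & n_union > 0,
              (n_gain + n_loss) / n_union, NA_real_)
  fake <- list(values = base_presence$values, years = base_presence$years,
               grid = base_presence$grid)
  per <- list(base_presence$period %||% range(base_presence$years),
              end_presence$period %||% range(end_presence$years))
  metric_from_cube(t, fake, metric_name = "turnover", units = "1",
                   period = per)
}

#' @describeIn turnover Turnover between the period means of two year ranges
#'   of one biomass field.
#' @param field A [biomass_field()].
#' @param base_period,end_period Length-2 inclusive year ranges, e.g.
#'   `c(2005, 2024)` and `c(2081, 2100)`.
#' @param threshold_fraction Presence threshold, default `0.001`.
#' @export
community_turnover <- function(field, base_period = c(2005, 2024),
                               end_period = c(2081, 2100),
                               threshold_fraction = 0.001) {
  pb <- presence(period_mean(field, base_period[1], base_period[2]),
                 threshold_fraction)
  pe <- presence(period_mean(field, end_period[1], end_period[2]),
                 threshold_fraction)
  turnover(pb, pe)
}

#' Change in community turnover rate
#'
#' Difference of two turnover fields: the turnover between the period means of
#' the late pair of periods minus the turnover between the period means of the
#' early pair (defaults: `2061--2080` vs `2081--2100`, minus `2011--2030` vs
#' `2031--2040`). Positive values mean community composition is changing
#' faster at the end of the run. Result lies in `[-1, 1]`.
#'
#' @param field A [biomass_field()].
#' @param early_pair,late_pair Lists of two length-2 inclusive year ranges.
#' @param threshold_fraction Presence threshold, default `0.001`.
#' @return A [metric_field] in `[-1, 1]`.
#' @export
turnover_rate_change <- function(field,
                                 early_pair = list(c(2011, 2030), c(2031, 2040)),
                                 late_pair = list(c(2061, 2080), c(2081, 2100)),
                                 threshold_fraction = 0.001) {
  for (p in c(early_pair, late_pair)) {
    if (p[1] > p[2]) abort("each period must have start <= end")
    if (!any(field$years >= p[1] & field$years <= p[2])) {
      abort(sprintf("period %d-%d is outside the field's years", p[1], p[2]))
    }
  }
  check_disjoint <- function(pair, label) {
    if (pair[[1]][2] >= pair[[2]][1] && pair[[2]][2] >= pair[[1]][1]) {
      abort(sprintf("%s periods overlap", label))
    }
  }
  check_disjoint(early_pair, "early")
  check_disjoint(late_pair, "late")
  t_early <- community_turnover(field, early_pair[[1]], early_pair[[2]],
                                threshold_fraction)
  t_late <- community_turnover(field, late_pair[[1]], late_pair[[2]],
                               threshold_fraction)
  out <- t_late
  out$value <- t_late$value - t_early$value
  attr(out, "metric_name") <- "turnover_rate_change"
  attr(out, "period") <- list(unlist(lapply(early_pair, paste, collapse = "-")),
                              unlist(lapply(late_pair, paste, collapse = "-")))
  out
}
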
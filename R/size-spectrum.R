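#' Theil--Sen robust slope
#'
#' Median of all pairwise slopes `(y_j - y_i) / (x_j - x_i)` over `i < j` with
#' `x_i != x_j` (an even number of pairs averages the two middle values, as
#' [stats::median()] does). Robust to isolated outliers; equals the ordinary
#' least-squares slope on exactly collinear data.
#'
#' @param x,y Numeric vectors of equal length with at least 2 finite points
#'   and at least two distinct `x` values.
#' @return The slope, a single number.
#' @export
#' @examples
#' theil_sen_slope(0:3, c(0, -1, -2, 10))  # outlier barely moves the median
theil_sen_slope <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) abort("need at least 2 finite points to fit a slope")
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- lower.tri(dx) & dx != 0
  if (!any(keep)) abort("all x values identical; slope undefined")
  median(dy[keep] / dx[keep])
}

#' Phytoplankton size spectrum of a community
#'
#' Sums biomass within each phytoplankton size class, giving the community
#' size spectrum. The representative ESD of a class is the geometric mean of
#' its member types' ESDs by default (natural on a log size axis), or the
#' log-uniform class centre. Zooplankton are excluded; total phytoplankton
#' biomass is preserved by the binning.
#'
#' @param biomass Numeric vector of per-type biomass, aligned with `registry`
#'   rows (zooplankton entries ignored).
#' @param registry A type registry mapping each phytoplankton type to a size
#'   class.
#' @param class_esd_um Optional numeric vector overriding the representative
#'   ESD per occupied class (e.g. class-boundary midpoints), aligned with the
#'   sorted occupied classes; default uses the geometric mean of member types.
#' @return A tibble of class `size_spectrum` with one row per size class:
#'   `size_class`, `esd_um`, `biomass`.
#' @export
bin_by_size <- function(biomass, registry, class_esd_um = NULL) {
  if (length(biomass) != nrow(registry)) {
    abort("biomass vector must align with the registry")
  }
  ph <- registry$trophic_role == "phytoplankton"
  if (any(is.na(registry$size_class[ph]))) {
    abort("registry has phytoplankton types without a size class")
  }
  cls <- sort(unique(registry$size_class[ph]))
  b <- vapply(cls, function(k) {
    sum(biomass[ph & registry$size_class == k])
  }, numeric(1))
  esd <- vapply(cls, function(k) {
    exp(mean(log(registry$esd_um[ph & registry$size_class == k])))
  }, numeric(1))
  if (!is.null(class_esd_um)) {
    if (length(class_esd_um) != length(cls)) {
      abort("class_esd_um must have one value per occupied size class")
    }
    esd <- class_esd_um
  }
  structure(
    tibble::tibble(size_class = cls, esd_um = esd, biomass = b),
    class = c("size_spectrum", class(tibble::tibble()))
  )
}

#' @describeIn bin_by_size Slope summary of a spectrum: raw Theil--Sen slope
#'   of `log(biomass)` vs `log(ESD)` over nonempty classes, the reported slope
#'   (raw + 3, assuming spherical cells), and the number of classes fitted.
#' @param x A `size_spectrum`.
#' @param ... Unused.
#' @export
glance.size_spectrum <- function(x, ...) {
  nonempty <- x$biomass > 0
  slope_raw <- if (sum(nonempty) >= 2) {
    theil_sen_slope(log(x$esd_um[nonempty]), log(x$biomass[nonempty]))
  } else NA_real_
  tibble::tibble(
    slope_raw = slope_raw,
    slope_reported = slope_raw + 3,
    n_classes_fit = sum(nonempty),
    total_biomass = sum(x$biomass)
  )
}

#' @describeIn bin_by_size Spectrum plot on log--log axes with the fitted
#'   slope in the title.
#' @param object A `size_spectrum`.
#' @export
autoplot.size_spectrum <- function(object, ...) {
  g <- glance(object)
  df <- tibble::as_tibble(object)[object$biomass > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$esd_um, y = .data$biomass)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "ESD (µm)", y = "biomass per size class",
      title = sprintf("size spectrum: reported slope %.2f (raw %+.2f + 3)",
                      g$slope_reported, g$slope_raw))
}

#' Gridded size-spectrum slope
#'
#' Per cell: average biomass over the period, sum into the 16 phytoplankton
#' size classes, drop empty classes, fit a Theil--Sen slope of `log(biomass)`
#' against `log(ESD)`, and report the slope plus 3 (the sphericity
#' correction). More negative reported values indicate relatively more biomass
#' in small types. Cells with fewer than two nonempty classes are `NA`.
#'
#' The presence threshold is *not* applied before binning by default (all
#' biomass is binned); set `apply_threshold = TRUE` to exclude sub-threshold
#' types first.
#'
#' @param field A [biomass_field()].
#' @param period Length-2 inclusive year range, or NULL to use the field as
#'   is (must then be a single time slice).
#' @param apply_threshold Exclude types below `threshold_fraction` before
#'   binning (default FALSE).
#' @param threshold_fraction Share threshold used when `apply_threshold` is
#'   TRUE.
#' @return A [metric_field] of reported slopes.
#' @export
spectrum_slope <- function(field, period = NULL, apply_threshold = FALSE,
                           threshold_fraction = 0.001) {
  stopifnot(inherits(field, "biomass_field"))
  if (!is.null(period)) {
    field <- period_mean(field, period[1], period[2])
  } else if (dim(field$values)[1] != 1) {
    abort("give a period, or a single-slice (period-mean) field")
  }
  reg <- field$registry
  ph <- which(reg$trophic_role == "phytoplankton")
  M <- phyto_matrix(field)                       # cells x n_phyto
  if (apply_threshold) {
    sh <- phyto_shares(field)
    M[!(sh$share >= threshold_fraction & sh$share > 0)] <- 0
  }
  cls <- reg$size_class[ph]
  cls_levels <- sort(unique(cls))
  ind <- outer(cls, cls_levels, "==") * 1        # n_phyto x n_classes
  B <- M %*% ind                                 # class-summed biomass
  log_esd <- log(vapply(cls_levels, function(k) {
    exp(mean(log(reg$esd_um[ph][cls == k])))
  }, numeric(1)))
  slopes <- apply(B, 1, function(b) {
    if (anyNA(b)) return(NA_real_)
    ok <- b > 0
    if (sum(ok) < 2) return(NA_real_)
    theil_sen_slope(log_esd[ok], log(b[ok])) + 3
  })
  metric_from_cube(slopes, field, metric_name = "size_spectrum_slope",
                   units = "1")
}
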
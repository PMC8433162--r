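#' Plankton functional-type registry
#'
#' The registry describes every plankton type in a biomass field: its
#' biogeochemical functional group, equivalent spherical diameter (ESD),
#' phytoplankton size class, and trophic role. The default registry mirrors a
#' trait-based ocean ecosystem configuration with 35 phytoplankton types in six
#' groups (2 prokaryotes, 2 picoeukaryotes, 5 coccolithophores, 5 diazotrophs,
#' 11 diatoms, 10 mixotrophic dinoflagellates) plus 16 zooplankton size
#' classes, spanning 0.6--2425 um ESD overall. Phytoplankton types are
#' (group x size class) combinations on 16 log-uniform size classes.
#'
#' @param n_size_classes Number of phytoplankton size classes (default 16).
#' @param phyto_esd_range_um Length-2 numeric, ESD (um) of the smallest and
#'   largest phytoplankton size-class centre. Class centres are log-uniform
#'   between the two.
#' @param zoo_esd_factor Zooplankton ESD as a multiple of the phytoplankton
#'   size-class centres (default 10, the preferred predator:prey size ratio).
#'
#' @return A tibble with one row per type and columns `type_id`, `name`,
#'   `group`, `esd_um`, `size_class` (NA for zooplankton), `trophic_role`.
#' @export
#' @examples
#' reg <- default_type_registry()
#' dplyr::count(reg, group)
default_type_registry <- function(n_size_classes = 16,
                                  phyto_esd_range_um = c(0.6, 228),
                                  zoo_esd_factor = 10) {
  stopifnot(n_size_classes >= 1, length(phyto_esd_range_um) == 2,
            all(phyto_esd_range_um > 0), diff(phyto_esd_range_um) > 0)
  class_esd <- exp(seq(log(phyto_esd_range_um[1]), log(phyto_esd_range_um[2]),
                       length.out = n_size_classes))

  # group -> occupied size classes (contiguous, as in trait-based models where
  # a type is a functional group / size class combination)
  group_classes <- list(
    prokaryote                 = 1:2,
    picoeukaryote              = 2:3,
    coccolithophore            = 3:7,
    diazotroph                 = 5:9,
    diatom                     = 4:14,
    mixotrophic_dinoflagellate = 7:16
  )
  phyto <- purrr::imap_dfr(group_classes, function(cls, grp) {
    tibble::tibble(
      group = grp,
      size_class = as.integer(cls),
      esd_um = class_esd[cls],
      trophic_role = "phytoplankton"
    )
  })
  zoo <- tibble::tibble(
    group = "zooplankton",
    size_class = NA_integer_,
    esd_um = zoo_esd_factor * class_esd,
    trophic_role = "zooplankton"
  )
  reg <- dplyr::bind_rows(phyto, zoo)
  reg <- dplyr::mutate(reg,
    type_id = dplyr::row_number(),
    name = paste0(.data$group, "_",
                  ifelse(is.na(.data$size_class),
                         sprintf("%02d", cumsum(.data$group == "zooplankton")),
                         sprintf("%02d", .data$size_class)))
  )
  reg <- dplyr::select(reg, "type_id", "name", "group", "esd_um",
                       "size_class", "trophic_role")
  validate_registry(reg)
  reg
}

phyto_groups <- c("prokaryote", "picoeukaryote", "coccolithophore",
                  "diazotroph", "diatom", "mixotrophic_dinoflagellate")

default_group_counts <- c(
  prokaryote = 2L, picoeukaryote = 2L, coccolithophore = 5L,
  diazotroph = 5L, diatom = 11L, mixotrophic_dinoflagellate = 10L
)

#' Validate a type registry
#'
#' Checks structural invariants: required columns, ESD within 0.6--2425 um,
#' every phytoplankton type mapped to one of the size classes, and (unless
#' `allow_custom_counts = TRUE`) the default functional-group composition of
#' 35 phytoplankton in counts \{2, 2, 5, 5, 11, 10\} plus 16 zooplankton.
#'
#' @param registry A registry tibble as from [default_type_registry()].
#' @param allow_custom_counts If TRUE, skip the default group-count check
#'   (used for reduced synthetic communities).
#' @return The registry, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(registry, allow_custom_counts = FALSE) {
  needed <- c("type_id", "name", "group", "esd_um", "size_class", "trophic_role")
  missing_cols <- setdiff(needed, names(registry))
  if (length(missing_cols) > 0) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(registry$type_id)) abort("registry type_id must be unique")
  if (!all(registry$trophic_role %in% c("phytoplankton", "zooplankton"))) {
    abort("trophic_role must be 'phytoplankton' or 'zooplankton'")
  }
  if (!all(registry$esd_um >= 0.6 * (1 - 1e-9) &
           registry$esd_um <= 2425 * (1 + 1e-9))) {
    abort("all esd_um must lie in [0.6, 2425] um")
  }
  ph <- registry[registry$trophic_role == "phytoplankton", ]
  if (!all(ph$group %in% phyto_groups)) {
    abort("unknown phytoplankton group label(s)")
  }
  if (any(is.na(ph$size_class)) ||
      !all(ph$size_class == as.integer(ph$size_class)) ||
      any(ph$size_class < 1L)) {
    abort("every phytoplankton type needs a positive integer size_class")
  }
  if (!allow_custom_counts) {
    counts <- table(factor(ph$group, levels = phyto_groups))
    if (!identical(as.integer(counts), unname(default_group_counts))) {
      abort(paste0(
        "phytoplankton group counts differ from the default {2, 2, 5, 5, 11, 10}; ",
        "pass allow_custom_counts = TRUE for a custom community"))
    }
    n_zoo <- sum(registry$trophic_role == "zooplankton")
    if (n_zoo != 16L) {
      abort("default registry requires 16 zooplankton types")
    }
    if (any(ph$size_class > 16L)) abort("size_class must be in 1..16")
  }
  invisible(registry)
}

#' A reduced registry for small synthetic communities
#'
#' Builds a minimal registry of `n_phyto` phytoplankton types (all labelled
#' `diatom` unless groups are supplied) with log-uniform ESDs, plus optional
#' zooplankton. Intended for toy scenarios and tests.
#'
#' @param n_phyto Number of phytoplankton types.
#' @param n_zoo Number of zooplankton types (default 0).
#' @param esd_range_um Phytoplankton ESD range (um), log-uniform spacing.
#' @param groups Optional character vector of group labels, length `n_phyto`.
#' @param n_size_classes Number of size classes to cut the ESD range into.
#' @return A registry tibble (validated with custom counts allowed).
#' @export
toy_registry <- function(n_phyto, n_zoo = 0,
                         esd_range_um = c(0.6, 228),
                         groups = NULL,
                         n_size_classes = min(16L, n_phyto)) {
  esd <- exp(seq(log(esd_range_um[1]), log(esd_range_um[2]),
                 length.out = n_phyto))
  breaks <- exp(seq(log(esd_range_um[1]) - 1e-9, log(esd_range_um[2]) + 1e-9,
                    length.out = n_size_classes + 1))
  cls <- as.integer(cut(esd, breaks = breaks, labels = FALSE))
  if (is.null(groups)) groups <- rep("diatom", n_phyto)
  reg <- tibble::tibble(
    type_id = seq_len(n_phyto + n_zoo),
    name = c(sprintf("phy_%02d", seq_len(n_phyto)),
             if (n_zoo > 0) sprintf("zoo_%02d", seq_len(n_zoo))),
    group = c(groups, rep("zooplankton", n_zoo)),
    esd_um = c(esd, if (n_zoo > 0)
      exp(seq(log(10 * esd_range_um[1]), log(2425), length.out = n_zoo))),
    size_class = c(cls, rep(NA_integer_, n_zoo)),
    trophic_role = rep(c("phytoplankton", "zooplankton"), c(n_phyto, n_zoo))
  )
  validate_registry(reg, allow_custom_counts = TRUE)
  reg
}
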
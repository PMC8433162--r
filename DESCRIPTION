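Package: planktodiv
Title: Phytoplankton Functional Diversity, Turnover and Size-Spectrum Analysis for Gridded Biomass Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gridded, depth-integrated plankton biomass
    fields from trait-based ocean ecosystem models: thresholded functional
    richness, Shannon diversity and evenness, presence-based community turnover
    and turnover-rate change, per-group appearance/disappearance mapping, and
    the phytoplankton size-spectrum slope (Theil-Sen). Includes area-weighted
    regional summaries, netCDF input/output, and a synthetic-data module with a
    parametric field generator of known diversity structure and a toy
    mechanistic community simulator (Monod growth, Holling type III grazing,
    size allometry, Arrhenius temperature response).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
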
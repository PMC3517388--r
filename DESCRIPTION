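Package: phcatch
Title: Geographic Accessibility and Spatial Coverage of Primary Health Facility Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models geographic accessibility and spatial coverage of a primary
    health care facility network on a raster landscape. Provides dasymetric
    redistribution of administrative-unit populations onto a 90 m grid using
    empirically sampled landcover density weights, anisotropic least-cost
    travel-time surfaces with slope-corrected walking (Tobler) and cycling
    speeds under three travel scenarios capped at 60 minutes,
    capacity-constrained catchment allocation (travel-time limit or catchment
    population, whichever binds first), and coverage/underservice reporting.
    Includes a seeded synthetic-landscape generator (terrain, landcover,
    roads, rivers, lake, sectors, facilities) so the full pipeline is testable
    without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
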
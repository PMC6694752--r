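Package: gensol
Title: Build DSSAT Soil Profiles from Gridded Soil Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates gridded soil-property layers (sand, silt, clay,
    organic carbon, bulk density, pH, cation exchange capacity at the six
    standard depth intervals) into crop-model-ready DSSAT soil profile
    (*.SOL) files. Implements the Saxton-Rawls pedo-transfer functions for
    wilting point, field capacity, saturation and saturated conductivity;
    classification of each grid cell into one of 27 generic soil profiles
    by texture, fertility and available-water-based rooting depth;
    remapping of generic-profile root growth factors onto the standard
    output layers; block-mean spatial aggregation from fine to coarse
    grids; and a bit-exact fixed-width *.SOL writer with a tolerant
    reader. Ships a seeded synthetic-grid generator so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
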
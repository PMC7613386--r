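Package: canopylut
Title: Look-Up-Table Retrieval of Maize Canopy Traits from Multispectral UAV Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieval of leaf area index (LAI), leaf chlorophyll content (LCC)
    and canopy chlorophyll content (CCC) from high-resolution multispectral UAV
    orthomosaics by look-up-table (LUT) inversion of a coupled leaf-canopy
    radiative transfer model (a PROSPECT-5 plate model coupled to the 4SAIL
    four-stream canopy model). Includes radiometric preprocessing (digital
    numbers to radiance, empirical line method with panel saturation handling),
    vegetation masking (hue-index and crop-height-model thresholds), Latin
    hypercube sampling of the model parameter space, mean-of-best-solutions
    inversion under plot-mean and per-pixel aggregation strategies, trait
    conversions (SPAD to LCC, CCC), evaluation statistics, and a fully
    synthetic scene generator so the whole pipeline is testable without field
    data. The leaf optical constants shipped with the package are synthetic
    stand-ins generated in code, not the published calibration tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
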
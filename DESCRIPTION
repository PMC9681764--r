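Package: halohab
Title: Habitability Windows and Salt-In Signatures of Halite Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transplant experiments on endolithic microbial
    communities living in halite (NaCl) nodules. Converts microclimate sensor
    logs (temperature, relative humidity, photosynthetically active radiation)
    into daily habitability windows via penalized-spline smoothing and
    deliquescence thresholds; computes community restructuring statistics on
    relative-abundance tables (archaea:bacteria ratios, Welch's t, Bray-Curtis
    dissimilarity, principal coordinates, ANOSIM); quantifies salt-in
    osmoadaptation signatures (protein isoelectric points, Trk potassium
    transport potential, osmoadaptation gene profiles); and ships a synthetic
    data generator reproducing the climatic regimes and community shifts the
    analysis assumes, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    mgcv,
    vegan,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
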
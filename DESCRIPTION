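Package: cyclesafe
Title: Bicyclist Road-Safety Surveillance: Exposure, Standardized Trends, Hotspots and Fatality Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for city-scale bicyclist injury surveillance.
    Estimates exposure denominators (bicyclist population and daily bicycle
    kilometers traveled) from weighted origin-destination travel surveys with
    network routing, polygon allocation and stratified interpolation; computes
    directly standardized monthly fatal and nonfatal collision rates and
    indirectly standardized mortality ratios with yearly summaries and
    between-year tests; detects spatial clustering of fatal collisions with
    Ripley's K, likelihood-cross-validated Gaussian kernel density surfaces,
    highest-density-region contours and quadrat dispersion tests; and models
    fatality risk with a binomial generalized additive mixed model with
    penalized smooths, a spatial smooth and nested random intercepts.
    Includes a synthetic-city generator with stored ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
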
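Package: gwquality
Title: Seasonal Groundwater Quality, Entropy-Weighted Indices and
    Nitrate Health Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing drinking-water suitability of well
    networks sampled across seasons: major-ion unit conversions and
    charge-balance quality control, WHO guideline screening,
    hydrochemical facies classification on the Chadha rectangle, ionic
    molar-ratio source diagnostics, an entropy-weighted water quality
    index (EWQI) fitted per season with Shannon-entropy parameter
    weights, USEPA-style non-carcinogenic nitrate ingestion risk
    (chronic daily intake, hazard quotient and hazard index for adults,
    children and infants), inverse-distance-weighted rasters of
    per-well quantities, and a copula-based synthetic well generator
    that reproduces per-season summary statistics so the whole
    pipeline runs without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
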
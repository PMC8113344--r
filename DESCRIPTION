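Package: annualcover
Title: Annual Land Use/Land Cover Mapping from Multi-Sensor Satellite Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for automatic annual land use/land cover (LULC) mapping from
    harmonized optical and SAR satellite time series: band-respective sensor
    harmonization, seasonal medoid and percentile-medoid compositing, spectral
    index computation, automatic training-sample migration by spectral distance,
    a four-collection random-forest probability-fusion classifier, stratified
    accuracy assessment, and post-classification change analysis. A synthetic
    scene generator with known class spectra, clouds, and planted change makes
    every pipeline stage testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    ranger,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
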
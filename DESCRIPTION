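Package: nepsink
Title: Vegetation Carbon Sink Estimation and Spatial Driver Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates vegetation net primary productivity (NPP) with a
    light-use-efficiency (CASA-style) model from gridded monthly climate and
    NDVI, derives net ecosystem productivity (NEP) by subtracting an empirical
    soil heterotrophic respiration term, and attributes the spatiotemporal
    variation of the resulting carbon sink: per-pixel least-squares trends
    with F-test significance classes, second-order partial and multiple
    correlations with a nine-class climate-driving typology, and
    optimal-parameter GeoDetector factor, interaction and risk detection.
    Includes a synthetic-scenario generator with recorded ground truth so the
    whole pipeline is testable without remote-sensing downloads, and
    text-based (Arc/Info ASCII grid) raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
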
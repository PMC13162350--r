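Package: scsbec
Title: Safe Climate Space Analysis for Bioenergy Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits per-crop "safe climate space" (SCS) envelopes -- the region
    of annual mean temperature and annual precipitation containing a stated
    fraction (default 95 percent) of a crop's gridded production mass -- from
    baseline climate and rainfed production rasters, classifies future
    multimodel-ensemble climates as inside or outside each envelope, and
    quantifies production-weighted exposure, cropland net primary production
    and negative-emission potential loss, and carbon/biodiversity trade-off
    classes on latitude-longitude grids. Ships a seeded synthetic-data
    generator with planted ground truth so the full pipeline is testable
    without external downloads, plus plain-text raster (ESRI ASCII grid)
    and table I/O and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
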
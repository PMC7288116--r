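Package: uavcanopy
Title: UAV Multispectral Orchard Canopy Measurement and Yield Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring per-tree canopy information in gridded
    (modern standardized) orchards from UAV multispectral products. Computes
    vegetation index images from co-registered GRE/RED/REG/NIR reflectance
    rasters, detects orchard rows and columns by cumulative grayscale
    projection with kernel-smoothed peak search (RCGP), converts the detected
    boundaries into point-cloud coordinates, derives per-tree morphometrics
    (canopy height, convex-hull projected area, circumscribed-ellipsoid
    volume), extracts color-moment and gray-level co-occurrence texture
    features, and predicts per-tree fruit yield with a three-layer
    back-propagation network trained by Levenberg-Marquardt. A synthetic
    orchard scene generator (band rasters, ASCII PLY point clouds, ground
    truth) makes the whole chain testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
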
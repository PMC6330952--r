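Package: canopyseg
Title: Individual Tree Crown Delineation, Crown-Stem Alignment and
    Species Classification from Hyperspectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Delineates individual tree crowns (ITCs) on airborne
    hyperspectral imagery by NDVI masking, local-maximum seed detection
    and seeded region growing, polygonizes crowns as convex hulls of
    pixel centers, and scores delineations against reference crowns with
    the Jaccard index and an area-based overall confusion matrix.
    Aligns delineated crowns to field-surveyed stems with power-law
    allometric gap-filling of missing crown radii and tree heights and a
    combined positional plus attribute Euclidean distance.  Classifies
    tree species from crown pixels with sum-normalized spectra,
    sequential forward floating selection of bands under the
    Jeffries-Matusita separability criterion, a support vector machine
    augmented with canopy height, and crown-level majority voting.
    Includes a fully specified synthetic-scene generator so the entire
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    kernlab,
    minpack.lm,
    polyclip,
    sp,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
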
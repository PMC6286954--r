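Package: crownseg
Title: Individual Tree Crown Delineation from Dual-Season Orchard Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates individual fruit-tree crowns from pairs of co-registered
    digital surface models (DSMs): a leaf-off (bare-branch) scene supplies the
    permanent scaffold of each tree, from which per-tree convex hulls and
    centroids are extracted via adaptive thresholding and morphological closing;
    a growing-season scene is then segmented by a marker-controlled watershed
    seeded from those hulls, with unreached fragments merged to the nearest
    crown. Computes per-tree crown widths parallel and perpendicular to the
    planting row, crown projection area (CPA), accuracy statistics against
    reference measurements (RMSE, relative RMSE, R squared), and crown growth
    rates over time. Includes a synthetic-orchard simulator that renders paired
    winter/summer height rasters with ground-truth labels so that every pipeline
    stage can be tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    yaml,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
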
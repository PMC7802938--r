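Package: plantunet
Title: PlantU-net Segmentation and Top-View Phenotyping of Seedling Maize
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact end-to-end encoder-decoder network (PlantU-net) for
    segmenting top-view images of maize seedlings, together with the full
    downstream phenotyping pipeline: per-plant coverage, circumscribed radius,
    bounding-box aspect ratio, azimuth-plane angle and RGB/HSV colour traits,
    plus pixel-level precision/recall/F1 evaluation and agreement statistics
    (coefficient of determination, normalized RMSE). Includes dataset
    expansion and elastic-deformation augmentation, sliding-window inference
    for images of arbitrary size, and a ground-truthed synthetic seedling
    scene generator so that training, segmentation, phenotyping and
    statistics are all testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    tiff,
    jpeg,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
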
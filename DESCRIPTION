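Package: track4d
Title: Annotation, Evaluation and Dynamics Analysis of 3D+t Particle Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for working with 3D+t (4D) microscopy stacks of
    moving particles ("blobs"): multi-page TIFF stack I/O with ROI cropping and
    negative-view normalization, volume opacity transfer functions, two-ray 3D
    marker placement, an XML trace interchange format with DiaTrack-style MAT
    and ilastik-style CSV importers, gold-standard trace evaluation via
    distance-weighted maximum-weight bipartite matching (precision, recall, F1,
    duration-based quality strata), a 14-descriptor trajectory feature set
    (route-based and hourly-law-based), and an exhaustive feature-subset by
    cluster-count search scored with clustering validity indices around an
    expectation-maximization Gaussian mixture. Includes a synthetic random-walk
    blob simulator that generates noisy 4D stacks with ground-truth traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
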
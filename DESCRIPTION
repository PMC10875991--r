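Package: ctpangio
Title: Cerebral Angiography, Vessel Centerlines and Straightening from 4D CT Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives arteriograms (CTA) and venograms (CTV) from dynamic CT
    perfusion series. Stages: Hounsfield-threshold skull stripping, vessel
    segmentation by the summed absolute response of each voxel's
    time-attenuation curve to a first-order derivative-of-Gaussian filter,
    artery/vein separation at the valley of the time-to-peak histogram,
    vessel-of-interest centerline extraction through cross-section centroids
    and Dijkstra shortest paths, and vessel straightening (curved planar
    reformation) by Rodrigues-rotation propagation of normal sampling planes.
    Ships synthetic vascular phantom generators with analytic ground truth so
    every stage can be validated without patient data.
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
    RNifti,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
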
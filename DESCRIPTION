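Package: nucfish
Title: Quantification of Chromosome Territories and Axial Compaction from 3D FISH Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify interphase chromosome organization in large
    polyploid nuclei from multi-channel 3D confocal FISH image stacks.
    Implements absolute-intensity thresholding, 3D connected-component
    object detection with minimum-size filtering, intensity-weighted
    centroids, DAPI-based nuclear geometry (sphere-equivalent and
    slice-fit radii, normalized radial positions), inter-probe and
    inter-chromosome centroid distances, axial compaction folds, spot
    counting with telomere normalization, intensity-weighted principal
    component shape descriptors, traced-path lengths, and group summary
    statistics. A ground-truthed synthetic-nucleus simulator renders
    nurse-cell-like and salivary-gland-like nuclei (Rabl/polytene or
    territorial chromosome configurations) as calibrated TIFF stacks so
    that every pipeline stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
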
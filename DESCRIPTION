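Package: ldscope
Title: Quantification of Lipid Droplet and Plastid Dynamics in Diatom Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microscopy-based quantification of lipid droplets (LDs) and the
    plastid in the diatom Phaeodactylum tricornutum. Implements brightfield
    cell morphometry with supervised pixel classification, shape-descriptor
    particle filtering and prolate-spheroid volume estimation; 3D confocal
    object modelling of BODIPY-stained LDs and the chlorophyll-emitting
    thylakoid region with touching-object splitting and barycenter distances;
    per-cell LD distribution statistics (counts, volumes, fraction of volume
    in the two largest droplets, LD-plastid distance classes); chlorophyll a
    and c quantification from 90% acetone extract spectra; and group
    statistics with Fisher's LSD compact letter displays and asterisk-coded
    t-tests. A synthetic image generator with known ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    Rcpp,
    igraph,
    jsonlite,
    randomForest,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
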
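Package: rootgrain
Title: Fine-Grained In Situ Root Phenotyping from Instance Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for fine-grained phenotyping of in situ root system scans.
    Tiles oversized polygon-annotated root images into fixed-size training
    patches, enforces one object per predicted instance mask by retaining the
    largest connected domain, reduces single-root masks to one-pixel-wide
    medial skeletons (K3M-style phased thinning with spur pruning), and derives
    per-root traits: length, diameter statistics from the Euclidean distance
    transform, projected and cylindrical surface areas, and curvature / radius
    of curvature from a quadratic fit to the skeleton. Also provides a
    closed-form layer, parameter and FLOP accounting of YoloV8seg instance
    segmentation variants, including an elongated-target variant with two
    extra downsampling stages and two large-target heads, and a seeded
    synthetic root-scene generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    yaml,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, Phenotype, Segmentation, ImageImport
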
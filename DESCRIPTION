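Package: cellstrain
Title: Per-Cell Strain Mapping and Monolayer Kinematics from Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mechanical response of confluent epithelial
    monolayers to substrate stretch from before/after fluorescence image
    pairs. Implements intensity-based affine registration (Mattes mutual
    information), membrane-marker cell segmentation, per-cell small-strain
    tensor estimation from dense displacement fields, cell-shape metrics,
    particle image velocimetry for collective migration speed series, and
    cortical-marker enrichment classification. Includes a seeded synthetic
    stretched-monolayer generator that provides ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
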
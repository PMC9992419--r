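Package: tenomac
Title: Spatial and Molecular Quantification of Tendon-Resident Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying tendon-resident macrophages in
    fluorescence and chromogenic section images and in high-throughput qPCR
    data. Provides watershed nuclear segmentation and reporter classification,
    in-fascicle abundance and density quantification, Euclidean-distance-map
    depth profiling with quartile enrichment ratios, EdU proliferation
    comparison, duplex in situ hybridization colour deconvolution with 50 um
    grid colocalization, DQ-collagen internalization classification, and a
    Fluidigm-style delta-CT / delta-delta-CT / PCA / ligand-receptor analysis.
    A synthetic-data generator with known ground truth emulates the study's
    section images, explant cell suspensions, and CT matrices, and packaged
    presets encode the measured study conditions for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    jsonlite,
    yaml,
    tiff,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
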
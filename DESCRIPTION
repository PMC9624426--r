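Package: socioglia
Title: Quantification of Microbiota Effects on Zebrafish Social Behavior,
    Forebrain Neuron Morphology, and Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking microbiota status to larval zebrafish
    social behavior and forebrain neuroimmune phenotypes. Implements dyad
    social-orienting and optomotor trajectory metrics with an in-motion
    filter; SWC neuron reconstruction I/O, arbor morphometry and exact 3D
    Sholl analysis; z-scored hierarchical clustering and principal-axis
    factor analysis of neuronal morphotypes; voxel-mask volumetrics,
    microglia density and affine registration of reconstructions;
    single-cell count-matrix subclustering, microglial fingerprint scoring
    and rank-sum condition markers; and a normality-gated group-comparison
    harness. Seeded synthetic-data generators emulate every input so the
    full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    methods,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    withr
Config/testthat/edition: 3
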
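Package: larvanet
Title: Whole-Body Connectome Derivation and Analysis for Segmented Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives synapse-weighted directed connectome graphs from
    CATMAID-style exports (SWC skeletons, connector and annotation tables)
    and analyses them: Leiden module detection, centrality ranking,
    source/sink classification, left-right stereotypy of connectivity and
    morphology, sensory-to-effector path classification, segmental
    connectivity censuses, and skeleton morphometrics (cable length with
    twig pruning, Gaussian smoothing, Sholl profiles, radial synapse
    density). Ships a synthetic segmented-larva connectome generator with
    planted modules and mirror-symmetric left-right connectivity so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
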
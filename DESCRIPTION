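Package: muskin
Title: Wild and Laboratory Mouse Skin Microbiota Analysis Pipeline
Version: 0.1.0
Authors@R: person("muskin", "developers", role = c("aut", "cre"),
    email = "muskin@example.org")
Description: A desk-scale, fully tested re-implementation of a wild versus
    laboratory mouse skin-microbiota analysis workflow for paired DNA
    (standing) and RNA (active) 16S rRNA amplicon profiles: frequency-method
    contaminant screening against nucleic-acid concentrations, a repeated
    rarefaction reliability filter for equal-depth normalization,
    core-community partitioning into shared and unique taxa, alpha and beta
    diversity with phylogenetic metrics and principal coordinates,
    PERMANOVA, group-equalized indicator-species statistics, species-level
    sequence matching with a near-tie reporting rule, microsatellite and
    mitochondrial genetic distances, (partial) Mantel distance-decay tests,
    and REML mixed-model variance partitioning. A synthetic-data generator
    plants quantified community, contamination, spatial and genetic
    structure so the entire pipeline is testable without sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    lme4,
    jsonlite
Config/testthat/edition: 3
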
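Package: coexdiv
Title: Coexpression Network Divergence Across Developmental Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signed weighted gene coexpression analysis of benthic-limnetic
    ecomorph divergence across two developmental stages. Builds signed networks
    from biweight midcorrelation, detects and merges coexpression modules,
    associates module eigengenes with a binary ecomorph trait under false
    discovery rate control, validates selected modules with two permutation
    tests (first-eigenvalue explained variance and Escoufier RV), quantifies
    cross-stage module preservation (Z summary) and consensus modules, explores
    global expression trajectories via principal coordinates and between-group
    PCA, and tests module/QTL genomic overlap with linkage-group-restricted
    randomization. Includes a synthetic-data generator with planted module,
    trait, preservation and overlap structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
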
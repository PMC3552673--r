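Package: cdtox
Title: Dose-Response Transcriptomics of Cadmium-Exposed Proximal Tubule Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dose-response microarray studies of
    cadmium nephrotoxicity in cultured human proximal tubule cells.
    Provides per-gene linear regression of expression on Cd2+
    concentration within exposure blocks, a rank-based hypergeometric
    gene-set enrichment test, cross-timepoint gene-list overlap
    significance, variance-filtered hierarchical clustering with Ward
    linkage on Pearson dissimilarities, and mutual-information network
    module detection, together with a synthetic microarray simulator
    that emulates a two-timepoint, four-dose, single-replicate design
    with MAS5-style signals and Present/Absent detection calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
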
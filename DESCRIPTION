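Package: cinscape
Title: Simulation and Analysis of Chromosomal Instability in Single-Cell Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying chromosomal instability (CIN) in clonal cell
    populations from single-cell copy-number data. Provides a branching-process
    simulator of cell lineages acquiring whole-chromosome mis-segregations,
    segmental aneuploidies and whole-genome doubling (WGD); a binned read-count
    copy-number caller (normalization, binary segmentation, ploidy-scale
    fitting, integer state calls); sample-level structural, aneuploidy and
    heterogeneity scores with consensus karyotypes and per-cell deviation
    censuses; hierarchical karyotype clustering with WGD detection via the
    consensus-doubling relation and DNA-content peak classification; and
    analysis of multiplex interphase FISH (miFISH) signal counts including
    clonal and subclonal aberration calls and clone enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
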
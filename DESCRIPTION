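Package: metalineage
Title: Differential-Coverage Binning and Phylogenomic Classification of
    Population Genomes from Multi-Sample Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for recovering and classifying population
    genomes from multi-sample metagenomes: differential-coverage contig
    binning, single-copy marker completeness and contamination estimation
    with a quality gate, gene-tree versus taxonomy congruence scoring for
    marker selection, masked concatenated-marker LogDet neighbor-joining
    phylogenetics with bootstrap support and monophyly tests, and
    reference-guided 16S rRNA read-pair recruitment with greedy
    patristic-distance clustering. A synthetic-data module generates every
    input with known ground truth so the whole workflow is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    phytools,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
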
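Package: minichrom
Title: Analysis of Fragmented Mitochondrial Genomes Organized as
    Minichromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying animal mitochondrial genomes that are
    fragmented into multiple small circular minichromosomes, as found in
    blood-sucking lice. Provides a synthetic genome and short-read
    simulator with known ground truth, a greedy overlap-layout assembler
    for circular contigs, annotation of coding and non-coding regions,
    compositional motifs, gene identity and tRNA cloverleaf structure,
    exact longest-shared-stretch detection between genes with a
    Monte-Carlo chance baseline, rotation-invariant comparison of gene
    arrangements across species with Dollo-style ancestral-state
    inference and rearrangement-event classification, and fragmentation
    versus life-history statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
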
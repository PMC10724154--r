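Package: subdom
Title: Subgenome Dominance Analysis for Allopolyploid Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing subgenome dominance in allopolyploid genomes:
    subgenome phasing from differential k-mers, transposable-element bias
    (subgenome biased index) and gene-flanking TE density, biased gene
    fractionation in sliding windows, tandem-array and pangenome
    classification, homoeolog expression bias and ohnolog fate calling,
    constraint on conserved noncoding sequences via a normalized edit
    distance, Hi-C A/B compartment calling and conserved-TAD classification,
    and weighted-methylation metaplots. Includes a synthetic allotetraploid
    data generator with a machine-readable ground-truth manifest so every
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
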
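Package: mutclust
Title: Detection and Characterization of Clustered Mutations in Densely
    Mutagenized Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects kataegis-like clusters of single-nucleotide variants in
    heavily mutagenized genomes by average-linkage (UPGMA) hierarchical
    clustering of per-chromosome variant coordinates, flat-cluster extraction
    at a cophenetic-distance cutoff, inconsistency-coefficient border
    refinement, and a mask/mutation-class/size/power filtering cascade.
    Also provides per-cluster statistics (size, power, homogeneity),
    transcriptional strand-bias phi statistics, metagene mutation-density
    profiles around CDS starts and 5'-UTRs, GC-normalized sequence-context
    matrices, modified rainfall plots, an expression-mutation association
    test, and a synthetic-data generator with planted clusters and ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
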
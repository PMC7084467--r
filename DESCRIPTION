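Package: famtrace
Title: Tracing the Evolutionary History of Plant Gene Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for reconstructing the
    evolutionary history of a large plant gene superfamily across multiple
    genomes: candidate screening against length, start-residue and
    C-terminal-motif criteria; Poisson-corrected distance phylogenetics with
    neighbor-joining and bootstrap supports; assignment of genes to putative
    ortholog loci (POLs) from tree clustering plus full-length amino acid
    identity; inference of intron gain and loss events from POL intron
    types; classification of within-species duplicates as tandem or
    segmental from annotated gene order; and dating of duplication events
    from Nei-Gojobori synonymous substitution rates with T = dS/(2*lambda).
    A bundled gene-family evolution simulator with whole-genome, tandem and
    segmental duplications, losses and intron events provides known ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    mclust,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
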
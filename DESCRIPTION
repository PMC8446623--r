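Package: gliascan
Title: Discovery, Epitope Profiling and Selection Analysis of Alpha-Gliadin Gene Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating tandemly duplicated alpha-gliadin (prolamin)
    gene families in chromosome-scale wheat assemblies and characterising
    their variation. Implements seed-and-extend homology discovery of
    intronless gliadin gene copies, positional clustering of copies into
    Gli-2 loci and subloci, overlap-aware scanning for celiac-disease
    T-cell epitopes including the immunotoxic 33-mer, codon-aware alignment
    with Kimura 2-parameter (gamma) distances and neighbor-joining trees
    with bootstrap support, Goldman-Yang codon site models (M7/M8) with
    likelihood-ratio tests and empirical-Bayes site posteriors of positive
    selection, and read-coverage classification of collapsed or
    haplotype-specific assembly copies. A synthetic-assembly generator with
    exact truth tables makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
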
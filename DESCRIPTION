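Package: OGDscan
Title: Genome Scans for Outliers of Genetic Differentiation and Selective Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genomic divergence scans from biallelic SNV
    genotypes: Weir-Cockerham F_ST, absolute divergence d_XY and nucleotide
    diversity pi in tiling windows; a SweepFinder-family composite likelihood
    ratio scan for selective sweeps on a per-chromosome grid using the folded
    site frequency spectrum; rank-based outlier calling including OGDs
    (windows that are simultaneously F_ST and d_XY outliers); permutation
    tests for genome-wide differentiation and for the association between
    OGDs and sweep targets; and gene-family/GO overrepresentation inside
    sweep-targeted OGDs. Includes a Balding-Nichols simulator with planted
    sweeps and annotated gene tables so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
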
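Package: epistress
Title: Integrative Analysis of miRNA Targeting and DNA Methylation in
    Stress-Responsive Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-resolved integration of miRNA target evidence and CpG
    differential methylation over a repeated-stress time course.
    Builds strand-aware gene models from GFF3 annotation, assigns
    differentially methylated CpG sites to promoters (2 kb upstream of the
    TSS) or gene bodies, intersects miRNA target predictions from two tools
    under a duplex-energy threshold, classifies functional genes at each
    sampling point as miRNA-only, methylation-only or dually regulated, and
    tests whether dual regulation exceeds chance with a permutation test
    against a hypergeometric-style null. A parameterised multi-omics
    simulator with planted effects (differential expression, differential
    methylation, methylation depression in miRNA-targeted genes, tunable
    dual-regulation enrichment) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
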
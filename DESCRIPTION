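Package: poolsweep
Title: Pool-Seq SNP Filtration, Allele-Frequency Characterization and
    Pooled-Heterozygosity Selective-Sweep Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pooled whole-genome resequencing of
    structured populations (lines). Provides multi-criterion variant
    filtration of per-line pooled SNP calls, benchmarking of call sets
    against a Sanger-style gold standard (sensitivity, specificity, false
    positive proportion, ROC), pooled alternative-allele frequency
    estimation and site-frequency summaries by functional annotation
    category, a pooled-heterozygosity (Hp) sliding-window selective-sweep
    scan with chromosome-wise permutation-derived significance thresholds,
    cross-line intersection and merging of significant windows into
    putative selective-sweep (pSS) regions with QTL overlap and
    prioritization of fixed putatively functional variants (pfVars), and a
    seeded Pool-seq simulator that generates all inputs with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    IRanges,
    S4Vectors,
    GenomicRanges
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
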
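Package: xydosage
Title: Autosomal Gene Expression Response to Sex Chromosome Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models autosomal gene expression as a function of X and Y
    chromosome copy number across aneuploid karyotype series. Provides
    negative binomial generalized linear models with median-of-ratios
    normalization and Wald tests, an autosome-only renormalization control,
    saturation (down-sampling) analysis, shared-response comparisons between
    effect catalogs (hypergeometric overlaps, weighted errors-in-variables
    Deming regression, variance explained, category enrichment), a
    five-dataset meta-analysis caller for X-inactivation escape from allelic
    ratios, repeat-array copy-number estimation from windowed read depth with
    GC-bias correction, karyotype principal component analysis with centroid
    confidence ellipses and nearest-centroid placement of structural-variant
    samples, and promoter-window assignment of regulatory peaks. A synthetic
    data module generates every input with known ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
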
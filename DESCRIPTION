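Package: senescreen
Title: CRISPRi Senescence Screen Analysis and Gene-Set Heritability
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline from pooled CRISPRi senescence-screen counts
    to gene-set classification and GWAS SNP-heritability enrichment. Fits
    per-gene selection coefficients (beta scores) by negative-binomial
    maximum likelihood with a permutation-based false discovery rate,
    validates screens by ROC analysis against gold-standard gene sets,
    classifies hits into inflammaging and common-aging sets by k-means on
    beta scores, builds distance-based SNP annotations from gene sets, fits
    stratified LD score regression with block-jackknife standard errors, and
    pools heritability enrichment across traits by random-effects
    meta-analysis. Includes synthetic-data generators (screen counts under a
    negative-binomial model, toy genomes, block-AR(1) linkage
    disequilibrium, and GWAS summary statistics) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    DESeq2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
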
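Package: cnvpop
Title: Population Analysis of Copy Number Variation in Two-Population Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population-scale copy number variation (CNV) analysis
    in a cultivated-versus-wild panel design: merging per-accession CNV calls
    into CNV regions (CNVRs) by stringent reciprocal overlap, recoding CNVR
    genotypes to VCF, classifying CNVR-SNP linkage disequilibrium with a rank
    statistic over the nearest flanking SNPs, quantifying copy-number
    population differentiation with the Vst statistic, annotating CN-variable
    and CN-differentiated genes with feature-impact accounting and term
    enrichment, principal component analysis of recoded genotypes, and
    benchmarking CNV call sets against a truth set. Includes a synthetic-data
    generator producing two-population CNV call sets, LD-structured SNP
    haplotypes and per-gene copy-number matrices with known planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
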
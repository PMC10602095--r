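Package: svcohort
Title: Structural-Variant Cohort Filtering, Concordance and Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-calling analysis of multi-sample structural-variant (SV)
    callsets from short-read whole-genome sequencing: resolution of
    multi-model duplicate records, per-type high-quality filtering on
    joint-genotyping site metrics, problematic-region masking,
    reciprocal-overlap concordance against reference callsets, per-sample
    call-count quality control, allele-frequency and size spectra, dosage
    principal components, SV-to-SNV linkage-disequilibrium tagging,
    single-variant association under additive and recessive models,
    stratified permutation-based copy-number burden tests, and ultra-rare
    gene-set aggregation with a SKAT-O-style statistic.  A synthetic-cohort
    generator emulates the statistical structure these stages assume
    (bimodal SV size spectrum, rare-skewed allele frequencies with
    singletons, Hardy-Weinberg genotypes, multi-model duplicates, planted
    burden and per-site effects, SNVs coupled to SVs at a target r-squared)
    so the whole pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
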
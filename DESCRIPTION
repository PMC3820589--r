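Package: poolseqval
Title: Validation of Pool-Seq Allele Frequency Estimates Against
    Individual Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the accuracy of population allele frequencies
    estimated from pooled sequencing (Pool-Seq). Implements SNP calling from
    synchronized pooled pileup counts ("sync" format) with minor-allele-count
    and per-pool coverage filters, concordance statistics between pooled and
    individual-based major allele frequencies (untransformed least-squares
    regression, arcsine-square-root transformed regression and paired t tests,
    coverage-effect correlation), a read-resampling analysis of estimation
    accuracy as a function of sequencing coverage, and a synthetic-data
    generator that emulates a pooled-sequencing validation design (diploid
    individuals pooled equimolarly per population, sequencing error,
    pipetting-weight variation, genotyping dropout) so the full pipeline can
    be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'pipeline.R'
    'poolfreq.R'
    'poolseqval-package.R'
    'resampling.R'
    'simulate.R'
    'sync-io.R'
    'tables-io.R'
    'validation.R'
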
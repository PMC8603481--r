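Package: sweepscan
Title: Selection Scans from Windowed Diversity Statistics with
    Coalescent Null Calibration and Copy-Number Masking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scans for hard selective sweeps in resequenced
    populations. Computes pool heterozygosity, nucleotide diversity and
    Tajima's D in sliding windows from population VCFs, calibrates
    one-tailed significance thresholds against neutral coalescent
    simulations under piecewise-constant demographic models given in ms
    dialect, collapses outlier windows into candidate sweep regions,
    masks false positives caused by segregating copy-number variation
    using GC-corrected read depth, and assesses gene-set and
    differential-expression enrichment of sweep genes by size-matched
    region resampling and gene subsampling. Includes a synthetic-data
    generator with planted sweeps, deletions and enrichment so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
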
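Package: gblupset
Title: GBLUP-Derived Marker-Set Association Tests for Genomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits genomic best linear unbiased prediction (GBLUP) and genomic
    feature BLUP (GFBLUP) linear mixed models by average-information REML,
    back-solves per-marker effects and t-statistics from the fitted genomic
    values, and tests marker sets (genes, GO terms, arbitrary features) for
    association with quantitative traits using four set statistics: the
    covariance association test (CVAT), a SKAT-type score statistic, sums of
    squared marker statistics, and counts of individually associated markers.
    Inference uses a competitive null obtained by circular permutation of
    per-marker contributions around the genome or by random marker-set
    sampling. Includes multi-trait CVAT for across-trait covariance, gene-level
    decomposition of the CVAT statistic, a simulation engine emulating panels
    of inbred lines with block linkage disequilibrium, and evaluation tools
    (F1 detection power, cross-validated predictive ability of GFBLUP models).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    data.table,
    fgsea,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
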
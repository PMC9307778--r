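Package: sereg
Title: Super-Enhancer Regulatory Genomics: Copy-Number, Perturbation-Screen
    and Hi-C Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for linking super-enhancers to their target
    genes in cancer genomes. Implements ROSE-style super-enhancer calling
    from co-occupied BRD4/H3K27ac peaks, fixed-width (15 kb) copy-number
    windowing of the hg19 autosomes with permutation amplification tests,
    a copy-number expression-QTL scan with a column-permutation empirical
    false discovery rate, a rank-change differential-expression statistic
    for replicate-free CRISPRi screens, Knight-Ruiz balancing and
    observed/expected normalisation of Hi-C contact matrices,
    distance-matched permutation calling of direct enhancer targets, and a
    modified Activity-by-Contact score. Ships a synthetic-data generator
    with planted ground truth so the whole pipeline runs and is tested
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
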
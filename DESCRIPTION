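Package: cfEnds
Title: Holistic Analysis of Cell-Free DNA Fragment End Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for holistic cell-free DNA (cfDNA) end fragmentomics.
    Extracts the four classes of fragment-end k-mer motifs (pre-end motifs,
    5' and 3' end motifs, post-end motifs) from aligned fragments and a
    reference genome, builds size-stratified motif spectra with
    sonicated-control bias correction, computes differential-motif
    statistics and the end-motif ratio, profiles 5'/3' cleavage proportions
    around CpG sites for fragmentomics-based methylation inference, models
    duplex (4-end) molecules with jagged ends, stem-loop adapter barcodes
    and nuclease cutting-signature attribution, and provides an SVM
    leave-one-out classification harness with ROC/AUC, bootstrap and
    downsampling analyses. A built-in simulator generates fragment cohorts
    with bimodal sizes, motif-biased cleavage and methylation-dependent
    cutting for method development and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
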
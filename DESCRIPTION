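Package: adavar
Title: Depth-Adaptive Variance Models for Cell-Free DNA Aneuploidy Screening
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aneuploidy calling for non-invasive prenatal testing (NIPT) from
    shallow whole-genome sequencing of cell-free DNA. Implements the classical
    fixed-variance normalized chromosomal value (NCV) z-score and a
    depth-adaptive alternative in which the mean and standard deviation of the
    target/reference chromosome-ratio statistic are recomputed for every sample
    from its own total read count using a multinomial read-mapping model, plus
    a constant bias term absorbing inter-individual copy-number noise. Includes
    BAM binning, GC LOESS correction, principal-component denoising,
    reference-set selection by coefficient-of-variation minimization,
    hypergeometric read subsampling, and a synthetic cohort simulator for
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
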
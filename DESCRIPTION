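Package: isoswitch
Title: Substrate-Switch Time-Course RNA-Seq Analysis of Bacterial Isoprene Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the substrate-switch time-course RNA-seq
    experiment used to identify isoprene-responsive genes in Rhodococcus sp.
    AD45: RPKM quantification with explicit handling of near-identical
    duplicated gene pairs, replicate depth and cross-correlation quality
    control, a housekeeping-calibrated fourfold multi-control criterion for
    substrate-responsive genes, an epoxyisoprene-only gene rule, a wild-type
    versus isoprene-monooxygenase-mutant inducer contrast, coverage-step
    detection of transcription boundaries and operon co-transcription,
    a homolog-colocalization screen for candidate isoprene degraders, and
    RT-qPCR standard-curve relative quantification. Includes a negative-
    binomial synthetic-data generator that reproduces the experiment's
    statistical structure with planted ground truth, so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
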
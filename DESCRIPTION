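Package: rvmeth
Title: Rare Regulatory Variants and Local DNA Methylation Outliers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links rare single-nucleotide variants that disrupt transcription
    factor binding sites (TFBSs) to extreme local DNA methylation values and
    to expression outliers of nearby genes. Implements rank-based per-CpG
    methylation outlier calling, per-TF permutation enrichment testing,
    position-weight-matrix disruption scoring (delta-PWM), sliding-window
    differentially methylated region (DMR) detection, distance-binned and
    flanking-variant analyses, region-overlap enrichment, and promoter
    methylation to expression-outlier integration. Ships a fully
    self-consistent synthetic cohort generator (genotypes, motifs, PWMs,
    beta-value matrix, blood cell fractions, expression) with a ground-truth
    table so that every stage of the pipeline is verifiable without access
    to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
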
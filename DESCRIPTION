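Package: mlpadose
Title: MLPA Dosage Analysis and Exon-Level Deletion Calling for the HEXB Gene
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for copy-number analysis of the HEXB gene from multiplex
    ligation-dependent probe amplification (MLPA) fragment data: a 17-probe
    panel model (14 exon-specific probes plus 3 reference-gene probes),
    peak-to-probe binning by expected amplicon size, dosage-quotient
    normalization against the reference-probe sum and a diploid control
    cohort, threshold-band copy-number calling, and deletion segmentation.
    Includes a seeded synthetic electropherogram peak generator for control
    cohorts and deletion carriers, a parser and catalog for HGVS-style
    Sandhoff-disease genotypes, and frame arithmetic for splice-event
    transcript consequences (exon skips, partial skips, cryptic acceptors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
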
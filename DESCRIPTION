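Package: m6Acoexpr
Title: Partial-Correlation Co-Expression Screening of RNA m6A Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes co-expressed with RNA N6-methyladenosine (m6A)
    regulators in case/control transcriptomes while controlling for a
    disease-gene covariate set via partial correlation, builds thresholded
    co-expression networks, intersects co-expressed genes with m6A peak
    annotations, and screens trans-eQTL SNPs falling inside fixed-width m6A
    peak windows. Includes a synthetic-data generator with ground-truth
    labels (latent confounding, direct regulator-target effects, case/control
    shifts, toy genome annotations) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
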
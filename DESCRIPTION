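Package: coexsnr
Title: Signal-to-Noise Scoring of Gene Expression Studies and Samples via
    Co-Expression Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the quality of gene expression studies by comparing their
    Fisher z-transformed gene-gene correlation matrices to a compendium-median
    reference correlation structure, with a disattenuation correction for the
    number of samples. Individual samples are scored by the change in the study
    score when they are removed, computed efficiently by downdating sufficient
    statistics, and normalized by the median absolute deviation. Includes
    preprocessing (log detection, median-polish normalization, probe filtering
    and probe-to-gene collapsing, cross-platform gene panels), a synthetic
    compendium simulator with controlled corruptions, and validation statistics
    (differential-expression fractions, leave-one-out naive Bayes posteriors).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
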
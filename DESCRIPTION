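Package: tissueclock
Title: Tissue-Specific DNA Methylation Age Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue-specific epigenetic clocks from Illumina-style
    methylation beta-value matrices. Provides platform harmonization
    (probe intersection, missing-value filtering and imputation, per-probe
    quantile normalization), genome-wide per-probe linear regression on age
    with F-tests and Benjamini-Hochberg false-discovery-rate control,
    bootstrap elastic-net stability selection of age-associated CpG markers,
    support-vector-regression age models tuned by cross-validated grid
    search, and downstream characterization of tissue-common versus
    tissue-specific aging markers (direction of methylation change, CpG
    island/shore and gene-structure enrichment, conservation-score
    comparison). A synthetic multi-tissue data generator with planted
    ground truth supports end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
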
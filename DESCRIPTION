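Package: patchglia
Title: Microglial Contamination Scoring and Analysis for Patch-seq
    Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies microglial mRNA contamination in Patch-seq neuronal
    transcriptomes with a marker-based per-cell contamination score
    normalized against a dissociated single-cell reference, derives the
    transcriptional signatures of contamination by rank-sum differential
    expression between high- and low-contamination cells, tests
    hypergeometric gene-set enrichment with false-discovery-rate control,
    partitions contamination variance across donors, cell types and
    technical covariates with restricted-maximum-likelihood linear mixed
    models (Nakagawa marginal and conditional R-squared), and estimates
    mixed-model associations between contamination and intrinsic
    electrophysiological features. Includes a seeded synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
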
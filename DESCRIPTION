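Package: motifsig
Title: Cross-Cohort Promoter-Motif Enrichment Signatures and Perturbation
    Matching
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline that screens transcription-factor
    promoter-motif gene sets for enrichment in triple-negative versus
    ER+/HER2- breast cancer across multiple expression cohorts.  It
    implements probe-to-gene collapsing, IHC-code phenotype
    classification, gene set enrichment analysis (signal-to-noise
    ranking, weighted Kolmogorov-Smirnov enrichment score, phenotype
    permutation null, leading-edge extraction), Stouffer weighted-Z
    p-value meta-analysis across cohorts, consensus promoter-motif
    signatures from genes enriched in the maximum number of cohorts, and
    signature matching against chemical/genetic perturbation gene sets
    to nominate candidate drugs.  A synthetic multi-cohort generator
    with planted motif-coherent modules allows the whole workflow to be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
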
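Package: hepamix
Title: Proteogenomic Integration of Multi-Omics Liver Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for integrating tandem-mass-tag proteomes,
    RNA-seq transcriptomes, and region-level DNA methylation from a surgical
    liver cohort. Provides per-gene mRNA-protein correlation screening with
    Kolmogorov-Smirnov pathway enrichment, consensus clustering of
    high-variance proteins into proteomic subgroups, permutation-tested
    metabolic pathway activity scores, differentially methylated region
    calling with a Gaussian-mixture classification of methylation-attenuated
    proteins, and recurrence-free survival analyses (Fisher, Kaplan-Meier,
    log-rank, multivariable Cox). Ships a seeded synthetic cohort generator
    that emulates the statistical structure the analyses assume, so every
    stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
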
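Package: stromasig
Title: T-Cell Infiltration and EMT/Stroma Signatures in Bulk Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the interplay between T-cell infiltration and
    epithelial-mesenchymal-transition (EMT)/stroma-related gene expression in
    bulk tumor transcriptomes. Derives marker gene sets from immune
    reference profiles, computes mean-log2 signature scores (infiltrating
    T-cell abundance, hallmark EMT, stromal/immune averages), removes
    tumor-purity confounding by regression residualization, ranks pathways by
    the concordance of member-gene correlations with a score, runs Cox
    proportional-hazards biomarker models (scaled hazard ratios, per-gene
    survival screens, Kaplan-Meier subgrouping), fits logistic response models
    with biomarker interactions and nested likelihood-ratio model ladders,
    summarizes species-partitioned patient-derived-xenograft read counts
    (mouse read fractions, species-specific RPM fold changes, read-based
    purity), and provides seeded synthetic-data generators emulating the
    structure of purity-confounded cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    survival,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
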
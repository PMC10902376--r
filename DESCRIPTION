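Package: radjoint
Title: Joint Radiomic-Genomic Subtyping by Anchor-Based Partial
    Multi-Modal Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for discovering tumor subtypes from partially
    overlapping radiomic and somatic-mutation cohorts. Provides a synthetic
    cohort generator with planted subtypes, pathway-supervised L2,1-norm
    imaging feature selection, anchor-based partial multi-modal clustering
    with two-step random-walk similarities and gap-statistic model selection,
    Kaplan-Meier / Cox survival characterization of subtypes, pairwise
    mutation co-occurrence and mutual-exclusivity mapping, and canonical
    correlation analysis linking the imaging and genomic views.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
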
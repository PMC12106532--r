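Package: sepsisimmune
Title: High-Dimensional Immunome Analysis of Paediatric Sepsis from
    Mass-Cytometry-Style Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for subset-level analysis of the
    circulating immunome in paediatric sepsis from single-cell cytometry
    event matrices: arcsinh preprocessing and per-subject downsampling,
    self-organising-map clustering with hierarchical metaclustering and
    rule-based mixed-cluster exclusion, subset-frequency tables, subject-level
    PCA and seeded two-dimensional embeddings, nonparametric differential
    abundance with Bonferroni control and standardised effect sizes,
    per-group signed correlation networks with density, modularity and
    negative-edge statistics, and subset-frequency diagnostic and prognostic
    classifiers with ROC evaluation.  A seeded synthetic-cohort generator
    emulates the statistical structure of a discovery cohort (planted
    abundance shifts, group-specific inter-subset covariance and clinical
    couplings) so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    igraph,
    jsonlite,
    withr,
    mclust
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
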
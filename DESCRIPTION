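Package: coabnet
Title: Differential Co-Abundance Network Analysis for Compositional
    Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers genus-level co-abundance networks from compositional
    microbiome data via L1-penalised latent-correlation estimation, pools
    per-region edge estimates with Fisher-Z random-effects meta-analysis,
    calls differential edges between phenotype groups with Cochran's Q and
    I-squared heterogeneity criteria, verifies robustness to covariates via
    partial correlation, screens candidate keystone genera from cross-
    sectional presence-absence structure, tests abundance and predicted-
    function differences after rank-based inverse normal transformation,
    and decomposes the variance of functional features into additive and
    genus-genus interaction components.  Includes a seeded synthetic-data
    generator with planted network structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    vegan,
    MASS,
    rlang
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
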
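Package: rasysgen
Title: Systems Genetics of Rheumatoid Arthritis: Meta-Analysis, Risk
    Scoring, Multiplicative Risk Simulation and Network Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for systems-genetics analysis of complex
    disease, developed around rheumatoid arthritis. Provides fixed- and
    DerSimonian-Laird random-effects meta-analysis with Cochran's Q and
    I-squared heterogeneity quantification and rule-based variant
    selection; odds-ratio-weighted genetic risk scores with ROC/AUC
    evaluation (DeLong confidence intervals and paired comparison) and
    Hardy-Weinberg exact testing; an exact constrained multiplicative
    multilocus disease-risk simulator that answers how many additional
    susceptibility loci are required to reach a target AUC; random walk
    with restart gene prioritization on protein-protein interaction
    networks with leave-one-out cross-validation; overlapping
    clique-based community detection with extended modularity; local
    hypergeometric gene-set enrichment; and seeded synthetic-data
    generators (case-control cohorts, heterogeneous meta-analysis
    studies, planted-module networks, gene sets) so the whole pipeline
    is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    metafor,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
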
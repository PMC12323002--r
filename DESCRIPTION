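Package: lineageEM
Title: Biomass-Constrained EM Estimation of Biological Function Abundances
    Across Taxonomic Lineages in Metaproteomics
Version: 0.1.0
Authors@R:
    person("Metaproteomics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the shared-peptide problem in mass-spectrometry-based
    metaproteomics. Implements a two-stage expectation-maximization algorithm
    that first estimates per-taxon relative biomass p(t) from MS1 extracted-ion
    chromatogram areas of confidently identified peptides, then estimates joint
    Gene Ontology term abundances p(k|t)p(t) under the constraint that function
    abundances sum to each taxon's biomass, and aggregates them to every
    canonical taxonomic level. Also provides the lowest-common-ancestor (LCA)
    baseline with normalized taxon and function abundances, E-value based
    control of the proportion of false discoveries, protein clustering and
    per-taxon unclustering, quasi-gold-standard construction, evaluation
    statistics (sensitivity, PFD, overlap-coefficient matrices, log2
    fold-change error metrics), and a synthetic-community generator with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
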
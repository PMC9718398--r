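Package: proxitome
Title: Proximity Interactome Analysis for Multi-Bait BioID Studies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing proximity-dependent biotinylation (BioID)
    interactomes across multiple baits and treatment conditions, built around
    the five classical RAD51 paralogs and their two heteromeric complexes
    (BCDX2 and CX3). Provides confidence filtering of post-search prey tables
    (iProphet probability and unique-peptide thresholds, contaminant removal),
    spectral abundance factor (SAF) quantification with zero imputation,
    multi-bait set algebra for complex-level interactome definitions and upset
    decompositions, differential BioID scoring under replication stress,
    drugZ-style CRISPR screen scoring and NormZ threshold classifiers,
    chemogenomic profile clustering, hypergeometric overrepresentation
    analysis with FDR control, Kaplan-Meier prognostic screening of prey-gene
    expression, bait-prey network assembly with database augmentation, and a
    synthetic-data generator with recorded ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, NetworkEnrichment, Survival,
    CRISPR, Software
RoxygenNote: 7.3.3
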
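Package: screentriage
Title: Virtual-Screening Triage: Property Filters, 3D Pharmacophore
    Matching, Consensus Rank Pooling and Diversity Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a structure-based virtual-screening
    triage workflow for kinase-focused compound decks: substructure-alert and
    physicochemical property filtering, 3D pharmacophore pose filtering with
    exclusion volumes, consensus pooling of top-N ranks from multiple docking
    scoring functions, K-medoids (PAM) diversity selection on Tanimoto
    distances over circular fingerprints, and the downstream compound-quality
    metrics (ligand efficiency, lipophilic ligand efficiency, hit rate,
    unbound brain-to-plasma partition) plus a molecular-formula mass
    calculator for HRMS calcd m/z values. A synthetic-deck generator with
    planted ground truth makes every stage testable without commercial
    libraries or docking engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
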
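Package: pathphylo
Title: Functional Phylogenomics of Metabolic Pathway Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps binary cellular-function characters (metabolic pathway
    presence/absence profiles) onto rooted prokaryotic phylogenies and
    quantifies their fit to the tree. Implements Fitch/Hartigan parsimony
    scoring and ancestral-state reconstruction for binary characters on
    multifurcating trees, the retention index with its consistency
    classification, mean-path-length node dating with clocked gain/loss
    events, and reduced colored subtrees summarising a pathway's
    evolutionary history. Also provides the surrounding pipeline: genome
    quality control, pathway-report loading, genus-level profile
    aggregation and Manhattan-distance hierarchical clustering,
    HMMER-based annotation transfer filters, protein-family cluster
    validation, Gene Ontology enrichment with the elim decorrelation
    procedure, tree-comparison metrics (Robinson-Foulds and branch
    score), and a synthetic corpus generator for testing every stage
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, Pathways, GO, Software
RoxygenNote: 7.3.3
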
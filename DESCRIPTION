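Package: oligoscore
Title: Confidence Scoring for Oligogenic Variant Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rule-based curation engine that grades the evidence supporting
    the pathogenicity of oligogenic variant combinations (variants in two or
    more genes jointly linked to a disease). Structured evidence extracted
    from publications (pedigree segregation, control cohorts, gene- and
    variant-level functional experiments) is scored on a four-level scale
    (Absent/Weak/Moderate/Strong), complemented with knowledge scores
    computed from local annotation tables (population-panel presence,
    clinical assertions, protein-protein interaction confidences, pathway
    memberships, pathogenicity predictor calls), and aggregated through
    auditable decision trees into functional and final metascores. Includes
    corpus-level harmonization across articles and gene combinations,
    referentially checked entity-table import/export, summary reporting, and
    a synthetic corpus generator with planted ground-truth scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'scoring-config.R'
    'constructors.R'
    'annotation-store.R'
    'knowledge-scoring.R'
    'manual-scoring.R'
    'aggregation.R'
    'worked-examples.R'
    'synth-fixtures.R'
    'report.R'
    'entity-tables.R'
    'cli.R'
    'evidence-model.R'
    'show-methods.R'
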
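Package: hallmarkConsensus
Title: Comparing Cancer-Hallmark Annotation Mapping Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing schemes that map the ten hallmarks of
    cancer onto Gene Ontology terms or pathway gene lists. Builds hallmark
    gene sets from ontology annotations with true-path propagation,
    quantifies consensus and divergence between schemes (term selection
    frequency, exclusive set intersections, consensus terms), partitions
    prognostic-hallmark genes into cancer-type subgroups compared by
    Jaccard index, computes Wang-method semantic similarity with
    best-match-average aggregation, runs a simplified weighted
    co-expression analysis (soft threshold, topological overlap, module
    detection, hub genes, hypergeometric enrichment), and diffs ontology
    versions restricted to selected terms and their first neighbours.
    A seeded synthetic-data generator produces every input with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'ontology.R'
    'schemes.R'
    'setcomp.R'
    'prognostic.R'
    'semsim.R'
    'coexpr.R'
    'evolution.R'
    'synthetic.R'
    'pipeline.R'
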
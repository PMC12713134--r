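Package: syllograph
Title: Sequence and Network Analysis of Behavioral Syllable Grammar
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of integer-coded behavioral syllable sequences, such as
    those produced by depth-video motion sequencing of freely behaving mice.
    Computes repetitive-alternation statistics and perseveration bout lengths
    from sliding three-syllable windows, builds per-animal directed weighted
    syllable transition networks, and derives node-level network measures
    (edge-count strength, average neighbor degree, average degree
    connectivity, closeness vitality via the Wiener index, betweenness
    centrality, closeness centrality). Includes per-animal syllable usage
    normalization with threshold binarization of flagged fast-locomotion
    ("racing") syllables, nonparametric group comparisons with the two-stage
    Benjamini-Krieger-Yekutieli false discovery rate procedure, and a
    seed-controlled synthetic cohort generator that emulates motion-sequencing
    output for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph
Suggests: testthat (>= 3.0.0), withr, jsonlite, yaml, optparse
Config/testthat/edition: 3
biocViews: BehavioralScience, Network, GraphAndNetwork
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alternation.R'
    'group-stats.R'
    'transitions.R'
    'io.R'
    'net-metrics.R'
    'synthetic-cohort.R'
    'racing.R'
    'pipeline.R'
    'syllograph-package.R'
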
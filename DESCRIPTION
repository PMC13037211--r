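Package: HerbNetProx
Title: Node-Weighted Network Proximity for Multi-Herb Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores multi-herb interventions against weighted disease
    modules on a protein-protein interaction network. Integrates
    multi-source disease-target evidence into node weights
    (multiplicative or additive), derives herb-related protein weights
    from dosage ratios, compound abundances and compound-protein
    interaction confidences, and evaluates interventions with coverage,
    Jaccard and (weighted) shortest-path proximity metrics against
    degree-aware permutation null models. Includes weight-perturbation
    robustness analysis and a synthetic-data generator for offline
    benchmarking of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'network-core.R'
    'disease-weighting.R'
    'herb-weighting.R'
    'network-metrics.R'
    'null-models.R'
    'sensitivity.R'
    'synthetic-data.R'
    'io.R'
    'workflows.R'
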
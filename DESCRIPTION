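Package: ceRNAsponge
Title: Inference of circRNA-miRNA-mRNA Sponge Networks from Multi-Tissue
    RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds competing endogenous RNA (ceRNA) networks from
    circRNA, miRNA and mRNA count matrices profiled across tissues under
    two conditions. Differential expression is called per RNA class with
    a self-contained negative-binomial exact conditional test; predicted
    miRNA-target pairs are filtered by Spearman rank correlation and
    candidate circRNA-mRNA pairs by Pearson correlation; shared-miRNA
    sponging is scored with a hypergeometric tail test; and the retained
    edges are assembled into audited tripartite networks. A seeded
    synthetic-data module simulates multi-tissue two-condition
    negative-binomial counts with planted differential expression and
    planted ceRNA triads, giving ground truth for precision and recall
    benchmarking. A temperature-humidity index helper characterises
    heat-stress exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'design.R'
    'simulate.R'
    'io.R'
    'normalize.R'
    'dispersion.R'
    'exact-test.R'
    'de.R'
    'correlation.R'
    'pairs.R'
    'hypergeom.R'
    'sponge.R'
    'network.R'
    'thi.R'
    'pipeline.R'
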
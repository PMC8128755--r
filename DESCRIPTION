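Package: synaptoNet
Title: Detection Filtering and Expression-Restricted Interaction Networks
    for the Synaptic RNAome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse coding and small non-coding RNA detected at
    synapses. Raw read-count matrices from total and small RNA-seq are
    normalized by library size to transcripts per million, abundance
    thresholds partition features into per-biotype detection sets, and
    experimentally validated interaction evidence from multiple source
    databases is filtered and intersected with the detected transcripts to
    build an expression-restricted microRNA/mRNA network. The package
    computes hub rankings, targeting-coverage statistics, exact Venn set
    comparisons against external curated lists, hypergeometric
    over-representation statistics, and pathway-fraction reports for
    stimulation experiments. A deterministic synthetic-data generator with
    planted ground truth makes the whole pipeline testable without access
    to sequencing archives or live database releases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, Network, GeneExpression, Sequencing
RoxygenNote: 7.3.3
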
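Package: ppihub
Title: Hub-Bottleneck Biomarker Prioritization from Differential
    Proteomics and Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("ppihub", "developers", email = "ppihub@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline that turns differential
    plasma-proteomics spot tables into a ranked set of candidate
    predictive biomarkers: differential-spot filtering (one-way ANOVA +
    fold-change cutoff), protein-protein interaction network ingestion
    and merging, hub selection by the mean + 2 SD degree rule,
    bottleneck selection by top-10% betweenness centrality, MCODE-style
    dense-module detection, hypergeometric/EASE over-representation
    analysis, and three-group validation statistics (one-way ANOVA with
    Tukey honest significant difference intervals, computable from raw
    values or from published summary statistics). A synthetic-data
    module generates every input the pipeline consumes so all stages
    are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
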
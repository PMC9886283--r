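Package: gmpsig
Title: Gene Module Pair Signatures for Transcriptional Drug Target Prediction
Version: 0.1.0
Authors@R:
    person("GMP", "Maintainers", email = "maintainers@gmpsig.org", role = c("aut", "cre"))
Description: Extracts target-specific transcriptional signatures (gene module
    pairs, GMPs) from compendia of perturbagen-induced differential expression
    signatures, such as CMap L1000 LEVEL 5 moderated z-scores. For each target,
    signatures of its perturbagens are compared with an enrichment-score based
    distance, outliers are removed by dendrogram cutting, co-expressed genes
    are detected with a weighted correlation (WGCNA-style) network, and a
    consensus ranking is obtained by Borda merging, from which the top and
    bottom gene modules are extracted. The package also characterizes module
    pairs in external gene networks, builds a GMP-overlap target network with
    hypergeometric and permutation significance plus affinity-propagation
    community detection, and scores query expression profiles against all GMPs
    to predict compound-target interactions (total and normalized correlation
    scores with permutation p-values). A synthetic-compendium generator with
    planted ground truth supports testing every stage without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
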
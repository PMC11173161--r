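Package: meqa
Title: Quality Assessment of Multimeric Protein Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the accuracy of individual multimeric protein
    structure models (estimation of model accuracy, EMA) without access to
    the native structure. Builds residue contact graphs from multi-chain
    PDB models (CB-CB cutoff with interface annotation), computes fixed
    node and edge feature layouts with pluggable per-residue feature
    providers, and fits two families of single-model predictors: graph
    regression backbones (graph transformer with TopK pooling, or a
    MetaLayer-style edge/node/global block) trained with weighted L1 and
    adaptive gradient clipping, and an energy-based regressor in logit
    space trained with a noise-contrastive objective and evaluated by
    brute-force grid inference. Includes CASP-style ranking metrics
    (modified ranking loss with a uniqueness rule, NDCG at 3) and a
    synthetic-data module generating toy complexes, graded decoys and
    stand-in quality labels so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
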
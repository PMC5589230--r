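Package: birw
Title: Bi-Random Walk Link Prediction on Microbe-Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate microbe-disease associations by running a
    step-limited bi-random walk on a heterogeneous network assembled from
    Gaussian interaction-profile (GIP) kernel similarities between microbes
    and between diseases, with a logistic regulation of the disease
    similarity. Ships the full evaluation protocol (leave-one-out and
    repeated k-fold cross validation with global candidate ranking, ROC and
    AUC), per-disease candidate tables, and a stochastic block-model
    generator of synthetic bipartite association networks for end-to-end
    testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
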
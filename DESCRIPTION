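Package: emgnn
Title: Explainable Multilayer Graph Neural Networks for Gene Classification
Version: 0.1.0
Authors@R:
    person("EMGNN", "Maintainers", email = "emgnn@example.org", role = c("aut", "cre"))
Description: Learns gene-level binary classifications (e.g. cancer versus
    non-cancer genes) from several gene-gene interaction networks jointly.
    A shared graph neural network embeds each network layer, a per-gene
    meta-node aggregates the layer-specific embeddings of the same gene
    through a second ("meta") graph neural network, and a multilayer
    perceptron classifies the meta-node state. Includes integrated-gradients
    attributions for node features and meta-edges, downstream attribution
    statistics (cancer-neighbor fractions, meta-edge variance/correlation
    analysis, one-way ANOVA across networks, preranked gene-set enrichment),
    a seeded synthetic multilayer benchmark generator, and a command-line
    interface. All model computation (forward, reverse-mode gradients, Adam)
    is implemented in base R with sparse matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
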
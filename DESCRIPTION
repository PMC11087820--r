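Package: dpisketch
Title: Global-Local Drug-Protein Interaction Prediction with Subgraph
    Sketches and Diffusion Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate drug-protein pairs in a bipartite interaction
    graph by fusing two feature channels. Local structural features come from
    MinHash and HyperLogLog sketches of k-hop subgraphs, which estimate
    shared-neighbourhood counts between a drug and a protein and feed a graph
    neural network encoder as structural edge features. Global features come
    from a transformer encoder whose all-pair attention realizes an
    energy-constrained diffusion over every node, connected or not. A
    multilayer perceptron fuses both channels (plus pluggable pretrained
    sequence embeddings) into an interaction score. Includes exact brute-force
    oracles for every estimator, a planted-community synthetic benchmark
    generator, a seeded training loop with early stopping, and a full
    evaluation metric suite (AUC, AUPR, ACC, SEN, PRE, SPE, F1, MCC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
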
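Package: sdprel
Title: Chemical-Protein Relation Extraction with Shortest-Dependency-Path Neural Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for extracting chemical-protein interactions from
    dependency-parsed biomedical abstracts. Reads CHEMPROT-style corpora
    (abstracts, gold entities and relations, CoNLL-U parses), builds a narrow
    five-sequence instance representation centred on the shortest dependency
    path between a chemical and a protein mention, encodes tokens with
    pre-trained word vectors plus part-of-speech and dependency-label
    embeddings, and classifies candidate pairs with a compact two-branch
    neural network (bidirectional LSTM or multi-window CNN cores) trained
    with class weighting, F1-monitored early stopping, per-epoch decision
    threshold tuning and seed ensembling. Includes the micro-averaged
    CHEMPROT evaluation, stratified precision/recall analyses, and a seeded
    synthetic parsed-corpus generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
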
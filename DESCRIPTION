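Package: ddipair
Title: Drug-Drug Interaction Prediction from SMILES Pairs with a
    Dual-Mode BiLSTM Pair Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary drug-drug interactions from pairs of SMILES
    strings. Molecules are tokenized with an atom-level byte-pair-encoding
    tokenizer, each drug is encoded by a bidirectional LSTM followed by a
    small multilayer perceptron, and the concatenated pair representation is
    scored by an affine-plus-sigmoid predictor. The two drug branches can
    share one set of weights (parameter-sharing) or carry independent
    weights (parameter-independent). Includes a hand-derived reverse-mode
    training loop with decoupled weight decay (AdamW) and a step learning
    rate schedule, from-first-principles binary-classifier evaluation
    (confusion analytics, ROC-AUC, PR-AUC, F1), Tanimoto fingerprint
    similarity, a synthetic balanced SMILES-pair generator with a planted
    substructure interaction rule, and command-line entry points for the
    simulate/train/evaluate/predict workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
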
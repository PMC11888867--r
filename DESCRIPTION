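Package: amylstm
Title: Attention-Based Bidirectional LSTM Classification of Amyloid Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based identification of amyloid-forming proteins with an
    attention-pooled bidirectional long short-term memory network implemented
    from first principles (embedding, gated recurrent cells, masked attention
    pooling, batch-normalised classification head, Adam/binary cross-entropy
    training), together with classical descriptor baselines (amino acid
    composition, amphiphilic pseudo-amino acid composition,
    composition/transition/distribution features, dipeptide deviation from
    expected mean) fitted with k-nearest neighbours, logistic regression,
    random forest, support vector machines and gradient boosting. Includes
    stratified data splitting, rank-based AUROC and threshold metrics, a
    multi-trial robustness runner, and a seeded synthetic protein-sequence
    generator with a plantable amyloid-like motif so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    class,
    ranger,
    e1071,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
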
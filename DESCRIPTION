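Package: chemrel
Title: Chemical-Protein Relation Extraction from Literature with Pretrained Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies chemical-protein interactions in biomedical
    abstracts annotated in the CHEMPROT tab-separated format. Candidate
    chemical-protein mention pairs are enumerated under a token-distance window,
    masked with placeholder tokens, and classified into five interaction groups
    (upregulator, downregulator, agonist, antagonist, substrate/product) or NONE
    by a recurrent neural network whose embedding and LSTM layers can be
    pre-trained on unlabelled text via a negative-sample discrimination task.
    Includes chemistry-aware tokenization with character spans, GloVe text-format
    embedding loading with an out-of-vocabulary policy, precision/recall
    threshold rebalancing fitted on development data, micro-averaged
    precision/recall/F evaluation with confusion matrices, and a synthetic
    corpus generator so the full pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
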
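Package: ltrEHR
Title: Interpretable Logistic Tensor Regression for Paired-Visit Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts binary clinical outcomes from irregularly spaced paired
    hospital visits using logistic tensor regression over medical-code
    embedding matrices. Provides a population-level model with one weight per
    medical code and a personalized model whose per-patient code weights arise
    from sample-wise Gram matrices (equivalently, an attention mechanism over
    code embeddings); sine/cosine positional encoding of the elapsed days
    between visits; skip-gram and CBOW code-embedding training with a
    phenotype-group pair-classification evaluation; L1-sparse proximal Adam
    fitting with grid search; patient-wise stratified cross-validation with
    standard machine-learning baselines and code-weight transfer; population
    and per-patient code-importance reports with add/remove-code risk
    simulation; and a seeded synthetic cohort generator with recorded ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
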
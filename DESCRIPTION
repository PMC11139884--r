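Package: ptsdlang
Title: Language Markers of Post-Traumatic Stress Disorder from Interview Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for studying linguistic
    markers of post-traumatic stress disorder (PTSD) in transcribed trauma
    narratives. Extracts a registry of per-document language features across
    seven families (textual, sentiment and emotion, lexical fields,
    morphosyntax, French periphrastic passive voice, speech disfluencies,
    readability, and word-adjacency speech-graph structure); screens each
    feature against diagnosis or DSM-5 criterion labels with Mann-Whitney,
    one-way ANOVA and chi-squared tests accompanied by Cohen-style effect
    sizes and Monte-Carlo post-hoc power; runs a repeated-run interpretable
    classification protocol (stratified splits, SMOTE oversampling,
    elastic-net logistic regression, random forest, and a cyclic-boosting
    additive model) with averaged ROC-AUC, averaged feature importances and
    misclassification error analysis; and trains a small text convolutional
    network with focal loss, document-level inference by sequence probability
    averaging, and deconvolution-based per-token saliency for pattern
    extraction. A synthetic-corpus generator with planted group effects
    provides ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
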
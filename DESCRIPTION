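Package: symsim
Title: Multi-Layer Similarity and Screening Alignment for ADHD Symptom Statements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies linguistic redundancy among DSM-5 ADHD symptom
    statements with a three-layer sentence-similarity framework (lexical
    word-alignment similarity, dependency-triple syntactic similarity, and
    embedding cosine similarity), fuses the layers with entropy-based
    weights, and flags redundant symptom pairs by a percentile threshold.
    Also implements a two-stage screening-questionnaire alignment pipeline:
    an embedding-based filter separating ADHD-consistent from non-ADHD
    symptom language, similarity-difference features, subtype classifiers
    for the inattention and hyperactivity/impulsivity domains, an
    embedding-overlap data-leakage control, and bootstrap robustness
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    glmnet,
    randomForest,
    e1071
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
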
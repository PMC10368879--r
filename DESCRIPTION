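Package: aderelex
Title: Drug-Adverse-Event Relation Extraction from Clinical Narratives
Version: 0.1.0
Authors@R:
    person("ADE", "Relex Developers", email = "aderelex@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for detecting
    drug-adverse-drug-event (ADE) relations in clinical notes: BRAT
    standoff corpus input/output, rule-based text cleaning and sentence
    segmentation with protected-token handling, dictionary tagging of
    drug/ADE/date mentions, enumeration and deduplication of
    within-sentence drug-ADE candidate pairs with derived negatives, a
    classifier zoo (character n-gram TF-IDF with an RBF-kernel
    maximum-margin classifier, a token-level convolutional network, and
    a bidirectional LSTM) behind a common registry, intra- and
    inter-corpus generalizability evaluation with inter-annotator
    agreement statistics and model-agreement cluster maps, and a
    seeded synthetic clinical-note generator so that every stage is
    exercised without access to protected health records.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
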
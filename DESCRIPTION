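Package: ademiner
Title: Adverse Drug Event Extraction from Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated named-entity-recognition and relation-extraction
    pipeline for detecting adverse drug events (ADEs) in clinical free text.
    Provides readers and writers for CoNLL-style BIO token annotations and
    brat standoff files, a seed-reproducible synthetic annotated-corpus
    generator emulating the statistical structure of an ADE-annotated
    clinical corpus, a pluggable lightweight trainable encoder for token and
    sequence classification, schema-constrained relation candidate
    generation, stacked end-to-end inference with a rule-based note-level
    ADE classifier, and strict/relaxed evaluation with per-class and
    micro/macro precision, recall, F1 and F2.
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
    withr
Config/testthat/edition: 3
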
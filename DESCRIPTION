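Package: sympner
Title: Clinical Symptom Named Entity Recognition with CRF, BPE-Dropout and
    Sub-Subword Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, dependency-light stack for span-based named entity
    recognition in clinical text, built around the techniques used by recent
    Spanish symptom-mention recognition systems: byte-pair-encoding (BPE)
    subword models with dropout regularization, a linear-chain conditional
    random field (CRF) output layer whose transition matrix is initialized to
    penalize invalid BIO transitions, optional character n-gram
    (sub-subword) feature embeddings fitted to a target embedding matrix by
    mean squared error, majority-vote ensembling of span predictions, and
    strict plus overlapping entity-level evaluation.  A seeded synthetic
    corpus generator and a small trainable transformer encoder make the whole
    pipeline runnable and testable on a laptop CPU with no external data or
    pretrained models.
License: MIT + file LICENSE
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
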
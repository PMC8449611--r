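Package: offlabelr
Title: Detecting Off-Label Drug Use Mentions in Online Health Community Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end text-mining pipeline for pharmacovigilance on
    patient forum (online health community) posts: a relevance classifier
    separating firsthand patient-experience posts from general chatter,
    consumer-language spelling normalization against a medical lexicon,
    dictionary-based recognition of drug and indication mentions with an
    embedding-similarity filter for non-medical terms, dependency-graph
    pairing of drugs with indications under a shortest-path jump threshold
    with cross-sentence anaphora substitution and negation handling, and
    comparison of retained pairs against a bundled FDA-approved-indication
    map to flag candidate off-label use with confidence buckets. Includes a
    synthetic annotated-corpus generator for evaluation and confusion-matrix
    scoring utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    igraph,
    e1071,
    glmnet,
    ranger,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
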
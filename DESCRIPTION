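Package: pathocode
Title: Constrained Decoding and Evaluation for Pathology Report Code Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for semantic annotation of pathology-report conclusions
    with thesaurus code series (topography, procedure, diagnosis). Builds a
    rule-filtered directed acyclic graph of historically observed code
    successions and uses it to mask greedy or diverse beam-search decoding,
    so that every generated annotation is a known, rule-valid code series.
    Includes a quantitative evaluation suite (corpus BLEU with paired
    bootstrap significance, per-code precision/recall/F1 with cumulative
    frequency binning, word/character error rates), case-based retrieval
    comparison of annotation sets against code queries, and a seeded
    generator of synthetic thesauri and annotated report corpora with a
    heavy-tailed code frequency distribution.
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
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
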
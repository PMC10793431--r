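Package: phenonorm
Title: Phenotype Concept Normalization to HPO Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for normalizing free-text phenotype mentions to Human
    Phenotype Ontology (HPO) identifiers and for benchmarking normalizers.
    Reads OBO-format vocabularies, renders template-based fine-tuning corpora
    (standard names, names plus a held-out half of synonyms, and
    typo-augmented variants), generates keyboard-proximity typo perturbations,
    provides an Okapi BM25 dictionary-lookup baseline with AND/OR token
    retrieval, adapts arbitrary text-completion models (including a small
    built-in trainable character-level model) as normalizers, and scores any
    normalizer with a six-category evaluation protocol (training names,
    held-out synonyms, simple and complex typos, cross-referenced terms,
    laymen's terms).
License: MIT + file LICENSE
Encoding: UTF-8
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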
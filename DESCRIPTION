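Package: expotax
Title: Taxonomy-Based Classification of Chemical Exposure Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic classification of biomedical abstracts according to a
    32-node taxonomy of human chemical-exposure information (biomonitoring and
    exposure routes). Implements a deterministic natural-language-processing
    pipeline (tokenization, part-of-speech tagging, lemmatization, gazetteer
    named-entity recognition, finite-state dependency parsing), seven families
    of sparse binary document features (lemmatized bag of words, noun bigrams,
    lexicalized grammatical relations, named entities, verb clusters, MeSH
    descriptors and chemical lists), per-node document-frequency feature
    selection, and an ensemble of independent binary radial-basis-function
    support vector machines with hierarchical positive-label propagation.
    Includes nested cross-validation, leave-one-feature-family-out ablation,
    inter-annotator agreement (Cohen's kappa), retrieval comparison against
    reference PMID lists, chemical-specific publication profiles, and a seeded
    synthetic corpus generator for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
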
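Package: radcoder
Title: Cross-Language Clinical Terminology Coding with a Text-Similarity Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps source-language clinical phrases to concept codes of a
    target-language standard lexicon (RadLex-style code + preferred name +
    synonyms). Phrases are translated by a hybrid of exact bilingual-dictionary
    lookup and a pluggable external translator, candidate translation/lexicon-term
    pairs are scored by four text-similarity measures (normalised Levenshtein,
    token-set Jaccard, CBOW word-embedding cosine, and taxonomy-based Wu-Palmer),
    and a small multilayer perceptron fuses the four scores into a
    synonym/non-synonym decision that drives code assignment. Includes glossary
    merging and fuzzy domain-dictionary extraction, precision/recall/F1
    evaluation against a gold standard, and a synthetic benchmark generator
    producing lexicon, taxonomy, corpus, glossaries and labelled synonym pairs
    at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
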
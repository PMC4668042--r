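Package: psycholex
Title: Construction and Analysis of Psycholinguistic Lexical Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds word-form lexicons with psycholinguistic variables from
    POS-tagged word-frequency lists. Computes frequency transforms
    (per-million, common logarithm, Zipf scale and Zipf rank), orthographic
    structure (letter counts, consonant-vowel coding, bounded bigram and
    trigram decomposition), corpus-relative measures (orthographic
    uniqueness point, Coltheart's N, OLD20, homograph profiles) and
    positional n-gram tables. Provides word-list and multi-criterion search
    engines with wildcard patterns, range operators, result statistics and
    CSV export; a pseudoword generator driven by positional n-gram
    structure; cross-corpus comparison analyses (Zipf-scale correlations,
    Fisher r-to-z contrasts, containment matrices, over- and
    under-estimation lists); and a synthetic Zipfian lexicon generator for
    testing and simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
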
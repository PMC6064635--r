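Package: ontotag
Title: Ontology Term Tagging and Ecological Statistics for Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dictionary-based annotation of citation abstracts with
    ontology terms and for downstream ecological statistics on the resulting
    term-frequency tables. Parses MEDLINE (tagged) and BibTeX citation exports
    organised into search cells (disease group x keyword category x pair of
    years), recognises lexicon terms with a deterministic longest-match
    tagger, builds document-presence count tables with rare-term filtering
    and document-based normalisation, and analyses them with Bray-Curtis
    dissimilarity, non-metric multidimensional scaling, PERMANOVA, Hellinger
    local contributions to beta diversity (LCBD), and per-term
    Kruskal-Wallis/Benjamini-Hochberg/Dunn differential testing. Includes a
    seeded synthetic-corpus generator with planted group and temporal effects
    for end-to-end validation.
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
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
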
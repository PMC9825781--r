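Package: ontotriage
Title: Ontology-Aware Annotation, Retrieval and Triage of Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained engine for dictionary-based concept annotation of
    biomedical text against an axis-partitioned ontology lexicon, Okapi BM25
    retrieval over an in-package inverted index with document-frequency query
    weighting and concept-identifier query expansion, learning-free linear
    re-ranking of retrieved documents by focus-axis specificity and concept
    TF-IDF density, and TREC-style evaluation (P@10, average precision, MAP,
    evolutionary rates). Includes a deterministic synthetic-fixture generator
    (mini-lexicons, corpora with planted concept occurrences, topics, qrels
    and reference document-frequency tables) so the whole pipeline is testable
    offline. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
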
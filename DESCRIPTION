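Package: phemap
Title: Partial Lexical and Logical Mapping Between Phenotype Terminologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps concepts of a fine-grained phenotype ontology (HPO-like)
    to a coarser clinical terminology (SNOMED CT-like) through a synonymy
    lexicon (UMLS-like). Implements complete lexical mapping via synonym
    groups, partial lexical mapping via rule-based shallow parsing and
    iterative term demodification, and partial logical mapping via
    closest-ancestor search over the source subsumption hierarchy, with
    level-stratified reporting, review-sample drawing, and a synthetic
    fixture generator with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
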
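Package: cellmine
Title: Dictionary-Based Mining of Cell Type and Cell Line Nomenclature in Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how cell type and cell line nomenclature is
    used in the biomedical literature. Compiles refined term dictionaries from
    cell ontologies (OBO flat files or plain term tables), tags document
    corpora with a configurable dictionary-based recogniser, and computes
    ontology coverage statistics (per-class subclass representation, overall
    identified fractions), publication-year usage trends and growth rates, and
    precision/recall/F-score evaluations against gold-standard annotations.
    Includes a synthetic ontology and corpus generator with planted ground
    truth so the whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stringi,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
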
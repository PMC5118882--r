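Package: cdeinventory
Title: Common Data Element Inventories from Clinical Trial Case Report Forms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds ranked inventories of common data elements (CDEs) from
    clinical-trial case report forms. Ingests CDISC ODM 1.3 study metadata and
    tabular CRF exports into a trial master model, normalizes and deduplicates
    data-element labels with Levenshtein, Jaro-Winkler and Metaphone similarity,
    maps forms to SDTM-style topic domains, ranks domains and elements by
    enrollment-weighted frequency, and scores the availability and frequency of
    documentation of each element against electronic-health-record site exports,
    emitting inventory tables and coverage heat-map matrices. A synthetic-corpus
    generator with full ground truth supports end-to-end evaluation when real
    CRFs cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
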
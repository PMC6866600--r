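Package: metarec
Title: Context-Sensitive, Ontology-Aware Value Recommendations for Metadata Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recommends values for fields of metadata templates (for example
    biosample attributes such as sex, tissue, cell line, cell type, disease and
    ethnicity) from repositories of previously filled-in template instances.
    Association rules with a single field-value pair in the consequent are mined
    from the repository with a level-wise Apriori search; a partially completed
    instance (the context) is matched to rule antecedents with the Jaccard index
    and candidate values are ranked by context-matching score times rule
    confidence. Free-text values can be annotated to ontology-term URIs with a
    dictionary annotator, and a mapping repository of equivalent term URIs
    enables recommendations across structurally different templates. Includes a
    majority-class baseline, a reciprocal-rank evaluation harness with binomial
    context enumeration, and deterministic synthetic-corpus generators with
    planted field dependencies, synonym variation and value sparsity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
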
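Package: ontoslim
Title: Ontology Slimming, Assembly and Quality Control for OWL Class Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts declared subsets ("slims") from OWL ontologies using a
    line-oriented instruction language with upward/downward closure and
    cross-ontology reparenting, merges import closures with strict
    deduplication, assembles slims together with curated content into a
    composite ontology, prunes duplicate-label classes under a
    primary-provider policy, runs structural quality checks (labels,
    definitions, cycles, dangling parents), and audits cross-ontology
    label overlap and free-text term coverage (exact and composite
    matches). Ships a seeded synthetic taxonomy generator so the whole
    pipeline is testable without downloading any real ontology.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
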
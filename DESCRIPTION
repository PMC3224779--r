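Package: ontodiff
Title: Reasoning-Based Quality Control for Logically Defined Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Validates ontologies whose terms carry cross-product logical
    definitions (genus plus relation/filler differentia, as in entity-quality
    phenotype modeling). Extracts the induced ancestral graph of each
    building-block ontology from the terms the definitions reference, merges
    the subsets, the definitions and optional cross-reference bridge
    equivalences into a composite ontology, classifies it with a built-in
    EL-fragment subsumption reasoner, and reports every disagreement between
    the inferred and the asserted hierarchy of the target ontology: implied
    but unasserted subclass links, asserted but unsupported links, and
    inferred term equivalences. Includes OBO flat-file input/output, a
    synthetic corpus generator with planted disagreements for end-to-end
    verification, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
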
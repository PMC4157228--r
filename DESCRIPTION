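Package: keggcomp
Title: Comparative Mapping of Enzyme Sets onto KEGG Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares a query list of Enzyme Commission (EC) numbers against
    the KEGG pathway annotation of a reference organism. For every metabolic
    pathway it reports shared and organism-unique enzymes, tests for
    enrichment or depletion with a two-tailed Fisher exact test (background:
    the full gene complement of the reference genome) followed by
    Benjamini-Hochberg adjustment, and builds color-coded KEGG pathway-map
    URLs. Enzymes that map to no pathway are compared separately. Definitions
    (organisms, pathways, EC-to-pathway links, per-organism annotations) are
    cached as tab-delimited flat files, refreshed from a KEGG-style REST
    service, or generated synthetically for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
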
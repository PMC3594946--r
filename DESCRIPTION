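Package: formulapair
Title: Formula-Pair Scoring, Rare-Herb Replacement and Simplification for
    Traditional Chinese Medicine Formulae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores pairs of Traditional Chinese Medicine (TCM) formulae by a
    position-weighted combinational degree (CD), scores pairs of herbs by a
    five-component attribute similarity (AS) over nature, taste, channel
    tropism, functions and indications, and scores the diseases two formulae
    treat by ontology-based semantic similarity (Sim, Wang's method by
    default). On top of these scores it implements two decision engines:
    replacement of a rare herb with a common herb drawn from a low-CD,
    high-Sim partner formula, and simplification of a middle-CD, high-Sim
    formula pair into a smaller formula of shared herbs plus matched high-AS
    herbs. A hypergeometric over-representation stage against GMT pathway
    collections supports mechanism inspection of the resulting formulae.
    Readers and writers for herb/formula tables (TSV/JSON), OBO disease
    ontologies, herb-target tables and GMT files are included, together with
    a bundled case-study fixture and a seeded synthetic-database generator.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
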
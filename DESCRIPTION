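Package: panelwatch
Title: Temporal Analysis of Clinical Gene Panels and ClinVar Variant Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tracks how a versioned clinical gene panel (PanelApp-style JSON
    version histories) and monthly ClinVar per-gene variant counts evolve,
    selects one representative panel snapshot per calendar month, classifies
    gene-status transitions between consecutive months, reconciles Ensembl and
    NCBI gene identifiers, joins panel membership with pathogenic/likely
    pathogenic (P/LP) allele counts per month, and quantifies change through
    percentage increases, burst detection and per-gene summaries, to inform
    the timing of genomic data re-analysis. A synthetic fixture generator
    emulates all inputs with a ground-truth event log so the full pipeline
    runs and is tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
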
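Package: hspcfate
Title: Fate-Commitment Dynamics of Hematopoietic Progenitors from
    Single-Cell qRT-PCR and Time-Lapse Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of early fate commitment in cytokine-stimulated
    CD34+ hematopoietic stem and progenitor cells. Converts Biomark-style
    single-cell qRT-PCR Ct exports into spike-normalised, floored dCt
    expression matrices; recovers population structure over time points via
    k-means with gap-statistic model selection, 2-D embeddings, and
    per-component gene contributions; computes a gene-gene correlation-burst
    indicator of imminent state transitions; quantifies dynamic morphology
    phenotypes (roundness, switch frequency, cycle length) on time-lapse
    lineage trees, classifies cells into stable-polarised / frequent-switcher /
    stable-round categories, estimates phenotype-inheritance transition
    matrices and two-state Markov switching rates; and ships a stochastic
    simulator of expression states and morphology-switching clone pedigrees
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
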
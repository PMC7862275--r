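Package: clonearch
Title: Clonal Architecture, Mutation Order, and Allele Dropout from
    Single-Cell Genotype Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs tumor clonal architecture from single-cell
    genotype matrices (wild-type / heterozygous / homozygous calls across
    a mutation panel, sampled at several timepoints). Cells are grouped
    into clones by exact genotype signature at presence or zygosity
    resolution, mutation acquisition order is inferred from mutated-cell
    frequencies, and a perfect-phylogeny clone tree with single
    mutation-gain and zygosity-escalation edges is built, with
    conflict detection and minimum-flip repair for noisy calls. Clone
    prevalences are tracked over time into nested, fishplot-ready tables
    and per-mutation zygosity trajectories. An allele-dropout (ADO) model
    links single-cell calls to amplification-free colony genotypes,
    giving a maximum-likelihood ADO rate with bootstrap intervals plus
    exact 2x2 Fisher and 2x3 Freeman-Halton tests. A synthetic-data
    generator with known clonal truth (clone tree, per-timepoint
    prevalences, per-allele dropout, miscalls, missingness, colony
    fitness bias) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
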
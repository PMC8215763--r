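Package: rumennet
Title: Temporal Co-Occurrence Networks and Keystone Taxa for Plant-Attached
    Rumen Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of temporal metatranscriptome count tables from
    forage-attached rumen microbial communities. Builds signed family-level
    co-occurrence networks from Spearman correlations of regularised-log
    expression, detects modularity clusters, identifies putative keystone taxa
    by leave-one-node-out perturbation of five network measures aggregated with
    a Borda count, assigns compact-letter significance groups to timepoints via
    maximal cliques of the non-significance graph, and profiles glycoside
    hydrolase, peptidase and LuxS gene families on the transcripts-per-million
    scale with two-way fixed-effect ANOVA and Tukey HSD groupings. A seeded
    synthetic-data generator emulating biphasic colonisation (primary and
    secondary sub-microbiomes, independent families, planted low-abundance
    keystone connectors, negative-binomial noise) makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
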
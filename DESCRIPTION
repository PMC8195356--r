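Package: cfptools
Title: Clonal Fractional Proliferation Assays: Stochastic Birth-Death
    Modelling, DIP-Rate Distributions, and Ontology Similarity
Version: 0.1.0
Authors@R:
    person("QuLab", "Artifact", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for attributing clonal drug-response variability to
    genetic, epigenetic, or stochastic sources. Provides an exact
    Gillespie simulator of linear birth-death cell populations and an
    in-silico clonal fractional proliferation (cFP) protocol;
    drug-induced proliferation (DIP) rate estimation, colony filtering,
    kernel-density summaries, and Mood's median test; two-sample
    Anderson-Darling comparisons with bootstrapped p-values; parameter
    scans over division/death rate constants for one- and two-state
    models with a bootstrapped acceptance rule; and a graph-based
    (Wang) ontology semantic-similarity pipeline with randomized term
    selection and a random-gene-list baseline. A synthetic-data module
    generates cFP datasets and toy ontologies with planted signal so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
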
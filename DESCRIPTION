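Package: satkit
Title: Assembly-Free Satellite DNA Discovery, Quantification and Comparison
Version: 0.1.0
Authors@R:
    person("satkit", "developers", email = "satkit@example.org", role = c("aut", "cre"))
Description: Characterises the satellitome of a genome from low-coverage unassembled
    short reads. Reads are cleaned and subsampled, clustered by shared canonical
    k-mers, and tandem-repeat (satellite DNA) clusters are recognised from the
    ring-like structure of their de Bruijn graphs; one consensus monomer is derived
    per family. Families are deduplicated, named by abundance rank and repeat unit
    length, quantified by masking reads against concatenated consensus references,
    and summarised as Kimura 2-parameter divergence landscapes. Libraries from
    several samples or species can be compared to detect shared families and
    male/female abundance asymmetries indicative of Y-linked satellites. A
    synthetic-data generator plants satellite families of known abundance and
    divergence so every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
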
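Package: tcsevo
Title: Comparative Genomics of Bacterial Two-Component Signalling Gene Sets
Version: 0.1.0
Authors@R:
    person("TCS", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cataloguing and comparing two-component system (TCS)
    gene sets across related bacterial genomes. Classifies TCS proteins
    (histidine kinases, hybrid kinases, response regulators and
    phosphotransfer proteins) from domain annotations, groups TCS genes into
    genomic foci (orphan, paired, complex, intricate), clusters proteins
    across genomes into orthologue/paralogue groups with a two-tier greedy
    similarity scheme, builds 16S rRNA distance matrices and bootstrapped
    neighbour-joining trees, and infers evolutionary events (gene gain/loss,
    duplication, horizontal transfer, organisation and architecture changes,
    relocations and inversions) between genomes. Includes a genome-evolution
    simulator with a machine-readable truth log so the whole pipeline can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
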
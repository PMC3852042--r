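Package: wgdfrac
Title: Fractionation Dynamics of Duplicate Genes After Ancient Polyploidy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the loss (fractionation) of duplicate genes
    after ancient whole-genome multiplication. Builds cross-genome homology
    sets from syntenic ortholog/paralog evidence and scores them by the
    number of genomes retaining more than one copy; parses Gene Ontology
    (OBO 1.2) files, propagates annotations to ancestor terms and tests
    per-term fractionation trends by regression of set-level term presence
    on fractionation score; fits a two-class maximum-likelihood model of
    paralog retention to per-species pair and triple counts and predicts
    retention-pattern curves; and simulates triplication followed by
    two-phase copy loss with class-biased functional annotation so that
    every stage of the analysis can be exercised on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lhs,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
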
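Package: pollenNet
Title: Pollen Metabarcoding Pipelines and Pollen-Transport Network Specialisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline from rbcL pollen-metabarcoding reads to
    ecological conclusions. Simulates reference libraries, per-insect pollen
    mixtures and error-bearing paired-end amplicon reads; merges and
    length-filters read pairs; assigns merged reads to plant taxa by a
    consensus rule over top-scoring local-alignment hits against a labelled
    reference library; aggregates per-insect pollen profiles; builds
    presence/absence bipartite pollen-transport networks and computes the
    specialisation indices H2' (network level) and d' (species level); and
    classifies individual insects as single- versus multi-plant visitors,
    modelling the classification with a binomial mixed-effects model with
    crossed random intercepts for site and insect species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    lme4,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
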
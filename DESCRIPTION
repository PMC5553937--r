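Package: tcrnet
Title: Similarity Networks and Sharing Analysis for TCR CDR3 Repertoires
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds Levenshtein-distance-1 similarity networks over TCR-beta
    CDR3 amino-acid sequences, quantifies clustering and centrality,
    classifies clonotypes by within- and cross-species sharing
    (private/public/cross-species-public), computes repertoire evenness
    (Gini) and convergent-recombination statistics, links externally
    annotated CDR3 sequences to network clusters, and simulates VDJ-
    rearranged synthetic cohorts as a null model and test fixture.
    Clonotype tables are read from plain TSV or AIRR Rearrangement TSV;
    networks are exported as GraphML or SIF with node-attribute tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
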
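Package: quartetco
Title: Quartet-Based Co-Estimation of Species Trees and Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based co-estimation of species trees and gene trees
    under the multispecies coalescent, one quartet of species at a time.
    Takes per-gene posterior distributions over gene-tree topologies (MCMC
    tree samples or per-topology log-likelihoods), computes for every
    species quartet the maximum-likelihood quartet species tree topology
    and internal branch length in coalescent units by marginalizing over
    gene-tree topologies, updates the per-gene topology posteriors given
    the inferred species tree, and amalgamates quartet trees into a full
    species tree (exact search for eight or fewer taxa, export files for
    external supertree tools otherwise). Includes coalescent simulators
    for long-branch-attraction (Felsenstein-zone) quartets and
    anomaly-zone caterpillar trees, a JC69 sequence simulator, and a
    four-taxon JC69 maximum-likelihood engine for building quartet
    posteriors directly from alignments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite
Config/testthat/edition: 3
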
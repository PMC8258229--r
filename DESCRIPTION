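Package: chemcophy
Title: Congruence of Herbivore Assemblages with Host Chemical Defenses and Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether insect herbivore assemblages track the
    chemical-defense profiles of their host plants or the hosts' shared
    evolutionary history. Builds chemical "defensograms" (dendrograms of
    plant families clustered on binary secondary-metabolite traits) with
    data-driven clustering-algorithm selection, runs Mantel matrix-correlation
    permutation tests of assemblage overlap against chemical and phylogenetic
    dissimilarity, and quantifies cophylogenetic congruence of bipartite
    herbivore-host networks with a Procrustean superimposition statistic
    (PACo) under a margin-preserving quasiswap null and with Random Tanglegram
    Partitions summarized by a normalized Gini coefficient. Includes a
    synthetic-data generator (Yule trees, tunable-cospeciation tanglegrams,
    binary trait evolution with convergence, distance-driven assemblages) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
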
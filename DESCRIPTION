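Package: coevonet
Title: Co-Evolutionary Networks from Phyletic Patterns of Gene Gain and Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-evolving pairs of gene families from phylogenetic
    profiles (presence/absence of orthologous gene families across genomes)
    on a fixed species tree. A stationary two-state continuous-time Markov
    model of gene gain and loss, with among-family rate variability and a
    branch-length scaling factor, is fitted by maximum likelihood. Posterior
    expected numbers of gain and loss events are mapped onto every branch by
    analytic stochastic mapping, and pairs of families with correlated event
    vectors are tested against an exchangeability-binned parametric-bootstrap
    null distribution with Benjamini-Hochberg false discovery rate control.
    The resulting co-evolution network can be summarised (degree statistics,
    clustering coefficient, degree-distribution fits), partitioned by a
    cluster-editing heuristic, and compared with external gene networks
    through enrichment ratios and Fisher's exact test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
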
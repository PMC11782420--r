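Package: glykin
Title: Glycosylation Reaction Networks, Golgi Kinetic Models and Sequential ABC Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of protein N-linked glycosylation.
    Parses LinearCode glycan structures and derives Oxford-style compositional
    tags; prunes template glycosylation reaction networks to minimal subgraphs
    by shortest-path union or minimum-flow reachability; compares networks by
    overlap, isomorphism and graph edit distance; identifies critical nodes
    from betweenness centrality and dominance-frontier membership; assembles
    and solves a four-compartment Golgi kinetic model with Michaelis-Menten and
    sequential-order Bi-Bi kinetics for competing protein entities; and
    estimates kinetic parameters with a staged approximate Bayesian
    computation sequential Monte Carlo scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
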
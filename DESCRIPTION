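Package: protnet
Title: Lattice Pseudocell Simulation and Self-Organization Metrics for
    Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic 3-D lattice cellular automaton (ProtNet) in which
    protein monomers diffuse, rotate, bind and dissociate under the rules
    of an input protein-interaction network, producing a dynamic
    "pseudocell" whose complexes can be scored for self-organization.
    Implements the Similarity Index between complex compositions, the
    Self-Similarity Index (SSI) of a pseudocell and the Inter-Cells
    Similarity Index (ICSI) between pseudocells; random-network
    generators (Erdos-Renyi matched to a reference network, and a
    Volz-style growth model with prescribed degree sequence and tunable
    transitivity); a panel of topology metrics (transitivity, average
    clustering coefficient, average path length, diameter, scale-free
    fitting index, modularity); and a multiple linear regression with
    backward elimination relating equilibrium SSI to network topology.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
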
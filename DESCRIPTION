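Package: coopbind
Title: Thermodynamic Modeling of Cooperative Multivalent RNA-Protein Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium thermodynamic model of cooperative, multivalent
    binding of multi-domain RNA-binding proteins (RBPs) to RNAs carrying
    several binding motifs. Effective local concentrations of tethered
    binding partners are computed from worm-like-chain polymer statistics
    (particle-in-a-sphere and Gaussian end-to-end models), the avidity
    (effective association constant) of an n-domain protein for an n-site
    RNA is obtained by exact enumeration of all 2^n binding configurations
    or by the dominant-path approximation, and the dependence of avidity
    and occupancy on binding-site density is modeled and quantified by
    Hill-coefficient fits. Analytic results can be cross-checked by exact
    stochastic simulation (Gillespie algorithm) of the full reaction
    network, and a validation pipeline predicts full-length dissociation
    constants of multi-domain proteins from their individual-domain
    affinities and geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
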
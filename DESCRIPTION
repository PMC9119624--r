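Package: polyphase
Title: Coarse-Grained Simulation of Specific and Non-Specific Polymer
    Self-Assembly
Version: 0.1.0
Authors@R:
    person("Maintainer", "Polyphase", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Langevin-dynamics simulator and analysis pipeline for
    coarse-grained bead-spring polymers that self-assemble through the
    interplay of a strong, short "specific" interaction patch and weak,
    promiscuous "non-specific" interactions. Provides system builders for
    two- and three-bead chain architectures and heterogeneous polymer
    mixtures, a BAOAB Langevin (NVT) integrator with truncated
    Lennard-Jones, harmonic stretching and angular bending terms under
    cubic periodic boundaries, replica-exchange (parallel-tempering)
    Langevin dynamics with Metropolis configuration swaps, and the full
    set of assembly order parameters: inter-chain specific/non-specific
    contact counts, largest-cluster size, radii of gyration of the
    specific patch, radial shell density profiles, dwell times and
    maturation times, plus free-energy profiles over contact order
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
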
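Package: nontransim
Title: Simulation and Analysis of Nontransitive Fitness Evolution in Killer Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how a series of adaptive steps can produce a
    descendant that loses in direct competition against its distant ancestor.
    Implements a multilevel (host cell x intracellular virus) serial-transfer
    simulator of killer-yeast experimental evolution, relative-fitness
    estimation from log-ratio competition time courses, detection of
    frequency-dependent selection and bistable equilibria, transitivity
    classification and dominance-cycle detection, killer-phenotype trajectory
    and transition audits, genotype-phenotype contingency statistics,
    amplicon-based viral variant-frequency quantification, mutation-spectrum
    statistics (transition:transversion bias, Nei-Gojobori dN/dS), and
    deterministic selective-sweep timing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
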
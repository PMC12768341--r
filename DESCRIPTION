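Package: oxphosim
Title: Thermokinetic Simulation of Mitochondrial Oxidative Phosphorylation
    and Bioenergetic Phenotype Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A flux-based thermokinetic ordinary differential equation model of
    mitochondrial oxidative phosphorylation in intact cells (electron transport
    chain complexes I, III and IV, the F1Fo ATP synthase, proton leak, adenine
    nucleotide and phosphate transport, coarse-grained cytosolic ATP turnover
    and hydrogen peroxide metabolism), together with a virtual-pharmacology
    layer (mitochondrial stress test, inhibitor fold-changes), graded-impairment
    sweeps with activity calibration, qualitative categorization of outputs
    against a physiological reference, and a hierarchical-clustering matcher
    that predicts which molecular defect(s) explain an experimentally measured
    bioenergetic phenotype.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
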
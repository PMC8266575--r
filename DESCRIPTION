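Package: g4tweezers
Title: Force-Spectroscopy Simulation and Inference for Polymorphic
    G-Quadruplex Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for single-molecule magnetic-tweezers force-ramp
    experiments on G-quadruplex (G4) forming DNA sequences that fold into
    multiple conformations (fully-folded G4s, guanine-vacancy-bearing
    intermediates, misfolded states). Provides worm-like-chain elasticity
    to convert unfolding extension steps into released nucleotide counts,
    Bell-model rupture kinetics under a linear force ramp with exact
    inverse-CDF sampling, censored maximum-likelihood fitting of
    multi-state Bell mixtures to unfolding-force distributions, sequence
    annotation of bulged G4s with expected step sizes per folding
    topology, first-order folding-probability kinetics, sigmoid
    melting-curve fits, a synthetic-data generator mirroring the
    force-ramp protocol, and packaged scenarios for reproducible
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
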
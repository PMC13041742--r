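Package: gatingspring
Title: Single-Molecule Mechanics of the NompC Gating Spring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of dual-trap optical-tweezers experiments on the
    mechanosensitive channel NompC and related ankyrin-repeat domains.
    Implements worm-like-chain and elastic-rod tether mechanics with exact
    inverses and compliance composition, the differential (DNA-subtraction)
    force-extension pipeline with rip detection and contour-length state
    assignment, constant-force two-state gating analysis via two-Gaussian
    mixture fits, a coupled ankyrin-spring Boltzmann gating model, generic
    Bell-Evans rupture kinetics, and a synthetic optical-tweezers data
    generator with full ground-truth records so every analysis stage can be
    validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
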
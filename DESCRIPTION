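Package: elecff
Title: Distributed-Charge Electrostatics and Induction Models for Molecular Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based models of intermolecular electrostatics and induction
    for small molecules and ions. Provides closed-form Coulomb kernels for point,
    Gaussian and Slater (1S, 2S) charge distributions together with a numerical
    quadrature oracle, split-charge equilibration (SQE) for generating atomic
    charges from electronegativity and hardness parameters, electrostatic
    potential (ESP) grid generation and constrained charge fitting, analytic
    core-plus-valence models for monatomic ions, polarizable Drude-like shells
    with an attractive Born-Mayer induction correction, and a hybrid genetic
    algorithm / Monte Carlo trainer that fits force-field parameters directly to
    dimer electrostatic and induction energy components. A synthetic reference
    generator produces dimer distance scans, randomly oriented contact dimers and
    per-frame energy component tables so that the full training pipeline can be
    exercised without external quantum-chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
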
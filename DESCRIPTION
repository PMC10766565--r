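Package: gridbind
Title: Absolute Binding Free Energies from Restrained Umbrella Sampling via Grid PMFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute protein-ligand binding free energies and
    dissociation constants from biased collective-variable trajectories.
    Pooled umbrella-sampling samples are reweighted with a self-consistent
    non-parametric estimator (multistate-reweighting fixed point), the
    three-dimensional grid potential of mean force of the ligand position is
    reconstructed by weighted histogramming, always-on restraints on ligand
    orientation and RMSDs are removed with analytic correction terms, and the
    standard-state volume term converts the pocket/bulk PMF difference into a
    standard binding free energy with block Bayesian bootstrap uncertainties.
    Includes Metropolis samplers on analytic toy potentials with quadrature
    oracles so every stage can be validated without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
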
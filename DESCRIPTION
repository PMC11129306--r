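Package: memgrad
Title: Membrane Thickness Gradients and Hydrophobic-Mismatch Peptide Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for studying lateral sorting of transmembrane peptides
    along membrane thickness gradients. Builds gradient-membrane blueprints
    (ordered lipid patches with flat-bottom positional restraints and
    piecewise-linear expected thickness profiles), provides a mean-reverting
    stochastic surrogate of mismatch-driven sorting together with a synthetic
    bead-level trajectory generator, and implements the full analysis stack:
    interleaflet-phosphate thickness profiles and peptide-centred 2D maps,
    peptide tilt/azimuth/projected-length/mismatch observables, exponential
    relaxation fits and lateral diffusion estimates, Boltzmann inversion,
    1D WHAM potentials of mean force, per-window tilt free energies, additive
    2D free-energy surfaces and thermally accessible-region extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
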
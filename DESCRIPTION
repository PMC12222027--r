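Package: flagmotor
Title: Symmetry, Stoichiometry and Step Analysis for Bacterial Flagellar Motors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for ring-shaped macromolecular
    assemblies such as the bacterial flagellar motor. Detects cyclic symmetry
    of 3D density maps from azimuthal power spectra, performs cylindrical
    averaging (lathing), measures radial density profiles, and estimates map
    resolution by Fourier shell correlation. Models the stoichiometry of
    concentric protein ring lattices (constant arc-spacing circumference-ratio
    model), symmetry mismatches and cog mesh registries, and the additive
    stator torque of the motor. Implements a bead-assay step-detection
    pipeline (orbit ellipse fitting, rotor angle extraction, wrapped von Mises
    kernel density estimation and weighted angular power spectra) together
    with synthetic density phantoms and stochastic stepping-rotor trajectory
    generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
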
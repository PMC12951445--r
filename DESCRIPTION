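Package: flavotune
Title: Electrostatic Tuning Analysis for Flavin-Binding Photoreceptor Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how a protein electrostatic environment tunes
    the excited states of a flavin chromophore, as in LOV (Light-Oxygen-Voltage)
    photoreceptor domains. Implements electrostatic spectral tuning maps (ESTMs)
    from probe charges on scaled van der Waals surfaces, electrostatic projection
    maps (EPMs) by nearest-neighbour averaging of potential grids onto the
    chromophore surface, averaged-configuration (ASEC) point-charge environments
    built from trajectory snapshots, per-residue RMSF flexibility and
    chromophore-proximity analysis, and linear-interpolation Cartesian reaction
    paths. Classical screened-Coulomb potentials stand in for external
    Poisson-Boltzmann solvers, whose OpenDX grids are also accepted as input.
    A seeded synthetic-data module generates toy chromophores, state
    difference-charge sets, point-charge environments and trajectories so the
    full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
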
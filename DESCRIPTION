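Package: acetylwall
Title: Structure and Transport Analysis of Acetylated Plant Secondary Cell Wall Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics models of chemically
    acetylated plant secondary cell walls. Implements acetylation bookkeeping
    (exposure-based hydroxyl selection, weight-percent gain, constant-volume
    water removal), mean-squared-displacement diffusion estimation with
    block-averaged uncertainties, periodic-boundary contact statistics and
    radial distribution functions, relative ion-binding free energies from
    occupancy ratios, ion residence (dwell) time distributions, and bulk
    water-pocket quantification. Ships seeded synthetic-trajectory generators
    with known ground truth (free diffusion, two-state binding kinetics,
    Boltzmann-weighted site occupancy, toy cell-wall configurations) so every
    estimator can be validated without microsecond simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
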
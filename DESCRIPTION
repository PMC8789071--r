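Package: forceramp
Title: Force-Ramp Single-Molecule Analysis of G-Quadruplex Unfolding in
    DNA Nanocavities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of optical-tweezers force-ramp
    experiments on a DNA-handle tethered telomeric G-quadruplex, with and
    without a stabilizing ligand and a DNA-origami nanocavity. Provides a
    Bell-Evans pulling simulator with worm-like-chain elasticity, rupture
    detection with change-in-contour-length and hysteresis-work
    measurement, seeded Gaussian-mixture deconvolution of rupture-force
    populations with species labelling and a proximity-versus-
    nanoconfinement partition, Jarzynski free-energy estimation with
    bias reporting, and thermodynamic-cycle dissociation constants with
    apparent-affinity and fold-change summaries, plus an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
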
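Package: sidearm
Title: Viscoelastic Characterization of Neurofilament Sidearms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing pipeline for steered-pulling and stress-relaxation
    studies of intermediate-filament sidearms. Parses per-atom trajectory
    frames in the LAMMPS text dump dialect, converts per-atom stress*volume
    output to group stress via Voronoi cell volumes, extracts engineering
    strain from atomic displacements, builds strain-rate-tagged stress-strain
    curves, fits relaxation moduli to Prony-series (generalized Maxwell)
    models by multi-start Nelder-Mead, and converts fitted relaxation moduli
    to time-dependent shear and bulk moduli through the elastic-viscoelastic
    correspondence principle, with a fixed-Talbot numerical inverse Laplace
    transform as an independent check. A synthetic-data module generates
    relaxation traces, two-stage tensile curves, and toy trajectory frames
    with known ground truth so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
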
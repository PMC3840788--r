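Package: septomo
Title: Septin-Gic1 Filament Cable Models and Cryo-Electron Tomography
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric models of yeast septin filament cables scaffolded by
    Gic1 (and Gic1-Cdc42) cross-bridges, together with a complete synthetic
    cryo-electron tomography pipeline used to validate them: Gaussian-blob
    phantom rendering, single-axis tilt-series simulation with contrast
    transfer function and noise, weighted back-projection reconstruction
    with missing-wedge bookkeeping, and a quantification suite
    (cross-correlation, beam-axis elongation, inter-filament spacing,
    subunit gap counts, capped-octamer/hexamer mixture classification, and
    mask-based density extraction). Volumes and image stacks are read and
    written as MRC files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
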
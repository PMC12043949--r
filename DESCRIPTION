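Package: nucleomech
Title: Quantitative Analysis of Nuclear Mechanobiology on Viscoelastic Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to characterize viscoelastic hydrogel substrates and their
    effects on the cell nucleus. Fits stress-relaxation curves with a
    two-element Maxwell-Wiechert biexponential and extracts the relaxation
    half time, computes initial moduli from compression ramps, normalizes
    oscillatory frequency sweeps, quantifies nuclear volume and chromatin
    compaction from confocal z-stacks, scores nuclear-lamina wrinkling from
    lamin-stained images, estimates FRAP recovery half times, and analyzes
    intranuclear particle trajectories via drift- and rotation-corrected
    time-averaged mean squared displacement with anomalous-diffusion
    power-law fits. Includes seeded synthetic-data generators with known
    ground truth for every input type.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
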
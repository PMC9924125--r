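Package: primescatter
Title: Island-Block Scatter Modeling for Passive Electron Intensity
    Modulators
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models electron scatter through the sides of the cylindrical
    tungsten island blocks that make up passive electron intensity
    modulators (PRIME devices) used in intensity-modulated bolus electron
    conformal therapy.  Provides the hexagonal-lattice device geometry and
    nominal intensity reduction factors, the pencil-beam in-scatter theory
    (side-scatter fraction, effective diameters and IRFs), the empirical
    quadratic modified-diameter surface in block diameter and beam energy,
    a Gaussian pencil-beam fluence and dose forward model, least-squares
    calibration of effective diameters against measured water-phantom dose
    grids, RMS and 2%/2mm agreement metrics, and a synthetic measured-data
    generator so the full calibration loop runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
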
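Package: cenquant
Title: Calibrated Photometry and Molecule Counting for Centromere Cluster
    Microscopy
Version: 0.1.0
Authors@R: person("Maintainer", "Cenquant", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative fluorescence microscopy pipeline for budding-yeast
    centromere biology: EMCCD frame calibration and ADU-to-photoelectron
    conversion, a trous (stationary B3-spline) wavelet separation of
    diffraction-scale spots from diffuse nuclear background, aperture
    photometry of centromere clusters, molecule counting against tetO/TetR
    calibration standards, photoconvertible-fluorophore (tdEos) state-model
    simulation with maturation-kinetics fitting, pulse-chase retention
    classification and targeted-photobleaching recovery analysis, and
    multifocal-plane PALM processing (plane assembly, localization,
    event grouping, fiducial drift correction, 3D cluster geometry).
    A synthetic-microscopy module generates every pipeline input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
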
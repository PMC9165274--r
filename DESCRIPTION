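Package: vmsot
Title: Volumetric Multispectral Optoacoustic Tomography Simulation and
    Tau-Probe Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and analysis pipeline for volumetric
    multispectral optoacoustic (photoacoustic) tomography of a far-red
    tau-binding probe in the mouse brain. Provides chromophore spectral
    libraries, atlas-labelled digital brain phantoms with bolus kinetics,
    an optical-acoustic forward model with band-limited detection,
    delay-and-sum back-projection reconstruction, per-voxel least-squares
    and vertex-component-analysis spectral unmixing, volume-of-interest
    quantification with the accompanying statistical battery, Gaussian
    full-width-at-half-maximum resolution characterization, and
    competitive radioligand binding fits with Cheng-Prusoff conversion
    and extra-sum-of-squares model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
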
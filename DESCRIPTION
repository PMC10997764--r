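Package: phytowave
Title: Decoding Plant Stress from Multiplexed Nanosensor H2O2 and Salicylic Acid Waves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts multiplexed near-infrared nanosensor fluorescence image
    stacks into hydrogen peroxide and salicylic acid concentration maps via
    Langmuir calibration, extracts stress-specific wave features (FWHM,
    production and decay rates, onset times, wave velocities), and simulates
    and fits a mass-action reaction network whose H2O2 and SA waveforms encode
    stress identity. A synthetic-data generator renders frame stacks with known
    ground truth for the four stress archetypes (mechanical wounding, Xcc
    infection, high light, high heat) so every pipeline stage is testable
    without raw sensor data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
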
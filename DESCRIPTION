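Package: corticox
Title: Dual-Modality Analysis of Cortical Blood Flow and Oxygen Tension
Version: 0.1.0
Authors@R: person("Corticox", "Developers", email = "corticox@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for dual-modality optical imaging of the
    cerebral cortex: laser speckle contrast imaging (raw frame stacks to
    speckle contrast, correlation time and relative blood flow) and
    phosphorescence-lifetime oximetry (averaged decays to lifetime and
    absolute oxygen tension via Stern-Volmer calibration).  Includes the
    camera-to-DMD affine coregistration geometry used for structured
    illumination targeting, tiled pattern generation, acquisition
    scheduling with feasibility checks, a Beer-Lambert estimate of
    excitation-light transmittance through surface vessels, and
    synthetic-data generators (gamma-statistics speckle stacks, noisy
    mono-exponential decays, scripted occlusion sessions) so the entire
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
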
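Package: ebnstrack
Title: Single-Particle Tracking, Sizing and Photon-Budget Analysis of
    Near-Infrared Fluorescent Nanosheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of near-infrared
    fluorescent Egyptian Blue nanosheets (EB-NS): fitting single-particle
    fluorescence saturation curves and estimating the number of luminescent
    Cu2+ centers from the photon budget; sizing single nanosheets from their
    Brownian motion via mean-square-displacement analysis and an
    anisotropy-corrected Stokes-Einstein relation; Van Hove displacement
    analysis of in-vivo tracking data with Gaussian-core fitting and
    non-Gaussian tail detection; plus spot detection and trajectory linking
    for image stacks, and synthetic-data generators (nanosheet populations,
    Brownian and active trajectories, diffraction-limited movies, saturation
    sweeps, nucleus maps) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
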
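Package: oslquench
Title: Energy-Dependent Luminescence Efficiency Correction for OSL Foil
    Proton Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 2D optically stimulated luminescence (OSL) dosimetry
    with LiMgPO4 silicone foil detectors irradiated in therapeutic proton
    beams. Implements the six-step OSL image-correction chain (sensor drift,
    per-detector background subtraction, detector localization, flat-field
    correction, spatial alignment, region-of-interest extraction), a
    one-dimensional range-energy surrogate transport model producing
    depth-dose curves and per-depth proton kinetic-energy spectra for
    pristine and spread-out Bragg peaks, water-equivalent depth bookkeeping
    for stacked foil/PMMA phantoms, the relative luminescence efficiency
    statistic and its composite logistic-plus-linear energy dependence with
    weighted nonlinear fitting, depth-wise ionization-quenching dose
    correction, and a synthetic-session generator for closed-loop validation
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
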
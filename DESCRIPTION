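Package: scintbeam
Title: Scintillator Camera Beam Monitoring for Ultra-High Dose Rate Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis stack for scintillator-camera beam monitors
    used in FLASH (ultra-high dose rate) radiotherapy. Generates synthetic
    camera frames with double-Gaussian beam spots, perspective foreshortening,
    inverse-square vignetting, Poisson photoelectron statistics and sparse
    background hits; builds the three-part calibration (flat-field correction
    matrix, planar homography, ADC to photoelectron to dose gain chain);
    runs the per-frame real-time analysis (pedestal subtraction, beam finding,
    weighted-moment centroids and widths, treatment-plan comparison and
    interlock) with a clock-tick latency ledger; and provides the offline
    characterization analyses: stepper-scan spatial resolution, pixel
    re-binning, band profiles with double-Gaussian fits, radiation-hardness
    ratio-of-ratios trends, dose-response linearity, and bremsstrahlung and
    neutron background budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
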
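Package: sdbquant
Title: Calibrated Quantification of Hydrogen Sulfide Species by
    MBB-HPLC-FLD Peak Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, peak integration, calibration and speciation
    arithmetic for hydrogen sulfide (H2S) assays based on monobromobimane
    (MBB) derivatization and reversed-phase HPLC with fluorescence
    detection.  Provides a seeded chromatogram and standards simulator,
    baseline-corrected trapezoidal peak integration with retention-time
    identity assignment, parabolic and linear calibration with
    leave-one-out cross-validation, detection and quantification limits,
    inverse prediction with uncertainty, three-pool sulfide speciation
    (free, acid-labile, bound sulfane sulfur) and repeated-measures
    cohort statistics with Dunnett contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
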
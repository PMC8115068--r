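Package: fdopa
Title: Simulation and Quantification Toolkit for [18F]FDOPA PET
    Treatment-Stratification Biomarkers
Version: 0.1.0
Authors@R:
    person("Imaging", "Methods Lab", email = "imaging.methods@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate striatal [18F]FDOPA PET dopamine-synthesis
    imaging as a treatment-stratification biomarker for psychosis, end to
    end on synthetic dynamic PET data with known ground truth.  Includes a
    dynamic-PET cohort simulator (frame schedules, gamma-variate cerebellar
    reference curves, Patlak-consistent striatal kinetics, frame-duration
    dependent noise, test-retest sessions), reference-region Patlak-Gjedde
    graphical estimation of the influx constant Ki at region and voxel
    level, simplified windowed uptake ratios (SUVR) with static-image
    signal-to-noise, test-retest reliability statistics (two-way ICC,
    percent test-retest difference), responder/non-responder discrimination
    (Cohen's d, ROC, sensitivity at the 100 percent-specificity operating
    point), voxel-wise classifiers under leave-one-out cross-validation,
    and an illustrative health-economic screening model with breakeven
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
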
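Package: rangewedge
Title: Measurement-Based Proton Range Uncertainty Evaluation on CT and CBCT
Version: 0.1.0
Authors@R: person("rangewedge", "developers", role = c("aut", "cre"),
    email = "rangewedge@example.org")
Description: Tools for quantifying proton range uncertainty from planar dose
    measurements. Provides geometry-aware image and dose containers with
    DICOM-style and plain-text I/O, Hounsfield-unit to mass-density
    calibration for CT and cone-beam CT (including group-based CBCT table
    fitting from volume-of-interest samples), an analytic Bragg-peak
    pencil-beam dose engine on density grids, digital head and thorax
    phantoms with a wedge-shaped target, 2D gamma-index comparison with a
    brute-force oracle, depth-sweep range-error estimation against a
    measured plane, and a daily CBCT dose-verification workflow with
    DVH-based coverage monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
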
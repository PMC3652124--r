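Package: petac
Title: Attenuation Correction Methods for Small-Animal PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and correction of photon attenuation in preclinical
    positron emission tomography. Provides an analytic phantom factory for
    mouse- and rat-sized cylinders, a parallel-beam projector implementing the
    attenuated Radon transform with attenuation-correction-factor sinograms,
    2D ordered-subsets expectation-maximization (OSEM) reconstruction, a
    quadratic Hounsfield-unit to 511 keV attenuation-coefficient calibration,
    fiducial-based rigid coregistration, threshold segmentation of emission
    images into uniform water attenuation maps, and the recovery-value and
    flatness statistics used to evaluate both correction routes end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
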
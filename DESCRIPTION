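Package: footmech
Title: Internal Foot Mechanics from Serial CT: Bone Registration,
    Ligament Morphing and Load-Case Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies internal foot mechanics from serial CT
    acquisitions of a loaded foot. Individually segmented bones from a
    reference scan are registered onto whole-skeleton threshold masks of
    each loaded configuration by hierarchical rigid iterative-closest-point
    minimization; a generic bone model carrying ligament attachment points
    is mapped onto the patient anatomy by normal projection and
    radial-basis-function mesh morphing; bone motion amplitudes, projected
    joint angles and ligament strains are derived per load case and
    compared between conditions with paired Wilcoxon signed-rank tests.
    A fully synthetic foot phantom with known ground truth supports
    end-to-end validation without any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
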
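Package: predose
Title: Organ-Level Preclinical Radiopharmaceutical Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an organ-level internal dosimetry workflow for
    preclinical radiopharmaceutical studies within the MIRD schema: import and
    validation of animal biodistribution measurements (%IA/g, SUV, %IA/mL),
    measurement time-point planning, cross-species transposition of
    SUV-equivalent biodistributions onto computational phantom source regions,
    time-integrated activity coefficient (TIAC) estimation by trapezoidal
    integration or multi-exponential nonlinear regression, a voiding-bladder
    excretory model, rest-of-body closure, and absorbed, equivalent, effective
    and RBE-weighted dose coefficients computed against user-supplied S-value
    tables.  A synthetic-biodistribution simulator with known ground-truth
    kinetics supports validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
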
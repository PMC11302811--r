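Package: mlcqa
Title: EPID-Based Picket-Fence Quality Assurance for Multi-Leaf Collimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantitative multi-leaf collimator (MLC) quality
    assurance from electronic portal imaging device (EPID) picket-fence
    images combined with linac delivery log files. Portal images are
    open-field normalized, per-leaf-pair abutment profiles are extracted and
    interpolated to a 0.01 mm grid, and three scalar features of the abutment
    valley (full-width half-maximum, valley area, valley depth) are calibrated
    against log-derived abutment widths with fifth-order polynomial curves
    under three data-processing schemes. An integration rule selects, per
    leaf, the method with the smallest absolute position error. A synthetic
    linac module simulates picket-fence and open-field portal images together
    with jittering delivery logs so the full calibration and validation loop
    runs without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
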
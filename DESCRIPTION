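Package: bbbfexi
Title: Filter-Exchange Imaging Models of Blood-Brain Barrier Water Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation and model fitting for blood-brain barrier
    water exchange measurements with filter-exchange imaging (FEXI). Implements
    the apparent exchange rate (AXR) model, a two-compartment exchange model
    (2CM), and a two-compartment exchange model with finite T1/T2 relaxation
    (2CMr, a Bloch-McConnell-type two-site solution), together with bounded
    multi-start Nelder-Mead fitting, noise-free bias experiments (relaxation
    times, fixed parameters), Monte-Carlo accuracy/precision studies under
    Gaussian noise, digital phantom generation, voxel-wise map fitting on 4D
    volumes, and scan-rescan repeatability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
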
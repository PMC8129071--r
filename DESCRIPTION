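Package: flowspill
Title: Automated Spillover and Spreading Matrix Estimation for Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes flow-cytometry spillover matrices from single-color
    controls without requiring well-defined positive and negative populations.
    Cells are gated automatically on forward/side scatter by density
    tessellation, an initial spillover matrix is estimated by Huber-robust
    linear regression of secondary versus primary detector signal, and the
    matrix is refined iteratively through the compensation-error identity
    T = -E U until the maximum residual compensation slope falls below a
    convergence threshold. Autofluorescence can be removed by treating an
    unstained control as an extra endogenous dye on a free detector. A
    companion estimator computes the spillover spreading matrix (SSM) by
    quantile partitioning and two linear regressions with a noise-floor
    adjustment. Includes a synthetic single-color-control generator with known
    ground truth, minimal FCS 3.0/3.1 input (and fixture output), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
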
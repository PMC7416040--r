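Package: mvarlearn
Title: Directed Functional Connectivity of Associative Learning in Block-Design Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of directed functional connectivity (dFC)
    during associative learning. Generates block-design, six-node network time
    series with known condition- and phase-specific lag-1 coupling for two
    groups, together with Gompertz-governed recall behavior; estimates pairwise
    directed coefficients with first-order multivariate autoregressive (MVAR)
    models per task condition (Encoding/Retrieval) and learning phase
    (Early/Late); fits Gompertz learning curves by bounded nonlinear least
    squares; and performs edge-wise group comparisons and covariate regressions
    with Benjamini-Hochberg false discovery rate control. Includes ROI sphere
    extraction from 4D NIfTI images and a reproducible end-to-end pipeline
    driven by a single configuration file.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
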
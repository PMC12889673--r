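Package: ssnspace
Title: Spatially Extended Stabilized Supralinear Network Models of Cortical
    Context-Dependent Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates, fits, and analyses spatially extended stabilized
    supralinear network (SSN) models of mouse V1 layer 2/3 with four
    recurrent cell types (E, PV, SST, VIP) on a retinotopic grid, driven by
    feedforward (L4), feedback (LM) and residual inputs. Provides Gaussian
    connectivity kernels, rate dynamics and steady-state solvers, a
    constrained gradient-based fitter for connection amplitudes and biases
    with multi-start ranking and ablation variants, subnetwork-Jacobian
    stability classification of cell-type-specific inhibition stabilization,
    and linear-response predictions of paradoxical effects under uniform and
    patterned (eigenmode) perturbations, including the determinant-sign
    parity diagnostic. Includes a synthetic-data generator emulating
    size-tuning experiments so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    igraph,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
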
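Package: cpmunet
Title: Cellular-Potts Vasculogenesis Simulation and a Periodic U-Net Surrogate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic Cellular-Potts (Glazier-Graner-Hogeweg) simulator of
    in vitro vasculogenesis on a periodic lattice, coupled to a secreted
    diffusive chemoattractant field, together with a convolutional surrogate
    model that learns to advance the simulation state 100 Monte-Carlo steps at
    a time. Includes the dataset builder that renders simulation snapshots
    into two-channel (vessel mask, field concentration) frames and pairs them
    across the prediction horizon, a circular-padding U-Net with PReLU
    activations trained with a combined binary cross-entropy and weighted
    mean-squared-error loss, and a quantitative evaluation suite: Dice score,
    field mean-squared error, torus-aware lacunae-area extraction and
    earth-mover's distance between lacunae-area distributions, plus divergence
    diagnostics over recursive surrogate rollouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
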
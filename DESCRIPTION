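Package: striatnet
Title: Corticostriatal Network Models of Oculomotor Sequence Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of learning dynamics in a model of the
    primate corticostriatal system performing an oculomotor sequence task.
    Provides a deterministic task environment (eight three-movement saccade
    sequences arranged in blocks), a temporal-difference (Q-learning) model
    of trial-by-trial choice with softmax action selection and maximum
    likelihood parameter fitting, a coupled pair of recurrent rate networks
    (a striatal value network and a prefrontal action-selection network)
    trained jointly by backpropagation through time, and a closed-loop
    autonomous mode in which decoded actions and rewards are fed back into
    the system. The analysis suite includes demixed principal component
    analysis (dPCA) with exact marginalization, latent-trajectory distance
    and compactness statistics, potential-surface estimation with fixed-point
    verification and Dijkstra minimal-path lengths between attractors, and
    canonical correlation analysis for comparing population activity between
    models or against recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
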
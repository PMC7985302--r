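Package: pgcoh
Title: Partial Generalized Coherence for Model-Free Frequency Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of direct (conditional) frequency coupling between
    continuously valued random processes. Implements mutual information in
    frequency (MIF) between windowed-FFT spectral increments and its
    conditional extension, partial generalized coherence (PGC), estimated
    either by a classifier-based Donsker-Varadhan divergence estimator with
    bootstrap averaging or by a Kraskov-style k-nearest-neighbour estimator.
    Also provides the linear-Gaussian reference path (coherence, partial
    coherence and their closed-form information transforms), three-process
    simulators with analytic ground truth, frequency-coupling graph
    construction with motif classification, and an estimator scaling
    benchmark on jointly Gaussian spectral increments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    glmnet,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
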
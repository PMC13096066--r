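Package: ndteflow
Title: Directed Transfer Entropy Connectivity and Functional Rich-Club
    Analysis for Epoched Electrophysiological Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates directed functional connectivity between cortical
    regions from epoched electrophysiological time series using normalized
    directed transfer entropy (NDTE) computed from Gaussian entropies of
    lag-embedded covariance matrices. Provides circular-shift surrogate
    inference with Stouffer p-value aggregation and false-discovery-rate
    masking, functional rich-club (FRIC) hub detection by inflow-ranked
    Monte-Carlo club growing, spatiotemporal cluster-based permutation
    tests for event-related potentials, spectral and phase entrainment
    measures (Welch bandpower, Morlet intertrial phase clustering, phase
    locking value), and correlation of reaction-time effects with the
    strongest inflow connections. A synthetic-data module simulates a cued
    auditory target-detection design with vector-autoregressive region
    time series and planted directed couplings and hub structure, so the
    whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
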
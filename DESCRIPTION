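Package: csntc
Title: Basal-Ganglia Selection of Cortical Reservoir Dynamics for Motor Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for cortico-striato-nigro-thalamo-cortical (CSNTC)
    loops in which a dopamine-gated basal ganglia circuit selects, by
    disinhibition of thalamo-cortical channels, which internal dynamics a
    cortical echo-state reservoir expresses. Provides leaky rate-unit
    dynamics, echo-state reservoir construction, a multi-channel basal
    ganglia module (StrD1, StrD2, STN, GPe, GPi) with multiplicative
    dopamine modulation, read-out learning by Tikhonov-regularized
    regression and by the online backpropagation-decorrelation rule,
    Oja/k-winner-take-all cortico-striatal plasticity, a planar 3-DoF
    kinematic arm with parametric target shapes, and the three simulation
    experiments (rhythmic trajectory selection, end-point posture control,
    and a two-module lesion study analysed with a two-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
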
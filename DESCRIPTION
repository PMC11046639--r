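Package: swarminf
Title: Collective Motion Through Active Inference and Generalized Filtering
Version: 0.1.0
Authors@R:
    person("swarminf", "developers", email = "swarminf@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of collective movement in which each
    individual runs generalized (Bayesian) filtering over the average
    distance to neighbours within angular visual sectors and steers by
    descending the gradient of its variational free energy. Social forces
    (attraction, repulsion, effective alignment) emerge from
    precision-weighted prediction errors rather than hand-crafted rules.
    Includes order-parameter metrics (polarization, angular momentum,
    milling probability, fragmentation), informed-agent target navigation,
    sensory-perturbation protocols, and online plasticity of the sensory
    smoothness parameter through free-energy descent on model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
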
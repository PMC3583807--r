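Package: bissepower
Title: Power and Accuracy of State-Dependent Diversification Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based power and parameter-recovery analysis for the
    binary-state speciation and extinction (BiSSE) model. Simulates
    ultrametric trees with a co-evolving binary character under
    state-dependent speciation, extinction and character-change rates,
    evaluates the BiSSE likelihood by adaptive Runge-Kutta-Fehlberg
    integration along branches with pruning at nodes, fits constrained and
    unconstrained rate models by cyclic Brent maximum likelihood with random
    restarts and warm starts, and estimates likelihood-ratio-test power
    against simulated null distributions. Includes the stationary
    character-frequency calculus used to construct rate asymmetries that
    yield a target tip-state bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
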